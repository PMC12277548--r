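test_that("phantom atlas is deterministic, partitions the mask, and regions are connected", {
  cfg <- tiny_config(seed = 4)
  a1 <- generate_phantom_atlas(cfg)
  a2 <- generate_phantom_atlas(cfg)
  expect_identical(a1$grid, a2$grid)

  counts <- region_voxel_counts(a1)
  expect_equal(sum(counts), sum(a1$grid > 0))
  expect_true(all(counts >= 150))

  # each region 6-connected, checked by the independent flood-fill oracle
  for (r in seq_len(cfg$n_regions)) {
    comp <- flood_fill_oracle(a1$grid == r, 6)
    expect_equal(max(comp), 1)
  }

  expect_error(generate_phantom_atlas(sim_config(grid_shape = c(8, 8, 8),
                                                 n_regions = 20)),
               class = "areascan_config_error")
})

test_that("genotypes are deterministic, near Hardy-Weinberg, with designed LD", {
  cfg <- sim_config(seed = 2, n_hc = 500, n_scz = 500, n_snps = 300,
                    missing_rate = 0, ld_pair_fraction = 0.2,
                    ld_flip_prob = 0.05, maf_range = c(0.5, 0.5))
  cohort <- generate_cohort(cfg)
  g1 <- generate_genotypes(cfg, cohort)
  g2 <- generate_genotypes(cfg, cohort)
  expect_identical(g1$dosage, g2$dosage)

  # copy-with-flip pairs at maf 0.5: dosage r2 ~ (1-2f)^2
  r2 <- vapply(seq(1, by = 2, length.out = 30), function(i) {
    cor(g1$dosage[, i], g1$dosage[, i + 1])^2
  }, numeric(1))
  expect_equal(mean(r2), (1 - 2 * 0.05)^2, tolerance = 0.05)

  # HWE holds across the maf range: exact p >= 0.001 for >= 99% of
  # SNPs at n = 1000
  cfgH <- sim_config(seed = 3, n_hc = 500, n_scz = 500, n_snps = 300,
                     missing_rate = 0, ld_pair_fraction = 0)
  gH <- generate_genotypes(cfgH, generate_cohort(cfgH))
  pvals <- vapply(seq_len(300), function(j) {
    g <- gH$dosage[, j]
    hwe_exact(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  expect_gte(mean(pvals >= 0.001), 0.99)

  # fixed-MAF heterozygosity: maf 0.5 -> het ~ 0.5
  het <- mean(g1$dosage[, seq(61, 300)] == 1)  # unpaired SNPs
  se <- sqrt(0.5 * 0.5 / (1000 * 240))
  expect_lt(abs(het - 0.5), 4 * se)
})

test_that("planted per-region case status recovers the designed odds ratio", {
  betas <- vapply(1:20, function(rep_i) {
    seed <- 40000 + rep_i
    cfg <- sim_config(seed = seed, grid_shape = c(16, 16, 16), n_regions = 5,
                      n_hc = 100, n_scz = 100, n_snps = 50,
                      affected_regions = 1,
                      causal_map = list("1" = list(snp = 5, effect = log(3))),
                      maf_range = c(0.3, 0.3), missing_rate = 0,
                      n_polygenic = 0)
    cohort <- generate_cohort(cfg)
    geno <- generate_genotypes(cfg, cohort)
    cohort <- plant_ba_phenotypes(cfg, cohort, geno)
    scz <- cohort$subjects$group == "SCZ"
    expect_false(any(cohort$case_flags[!scz, "1"]))  # HC never cases
    y <- as.numeric(cohort$case_flags[scz, "1"])
    if (length(unique(y)) < 2) return(NA_real_)
    logistic_fit(y, cbind(1, geno$dosage[scz, 5]))$coefficients[2]
  }, numeric(1))
  expect_equal(mean(betas, na.rm = TRUE), log(3), tolerance = 0.25)
})

test_that("planting is deterministic and warns when a region realizes no cases", {
  cfg <- tiny_config(seed = 9,
                     causal_map = list("1" = list(snp = 3, effect = log(2))))
  cohort <- generate_cohort(cfg)
  geno <- generate_genotypes(cfg, cohort)
  c1 <- plant_ba_phenotypes(cfg, cohort, geno)
  c2 <- plant_ba_phenotypes(cfg, cohort, geno)
  expect_identical(c1$case_flags, c2$case_flags)
  expect_identical(c1$subjects$group, c2$subjects$group)
})

test_that("gray-matter images honor the noiseless and planted-effect designs", {
  # noiseless, no effects: all subjects identical to the baseline map
  cfg0 <- tiny_config(seed = 5, noise_sd = 0, gm_effect_d = 0,
                      covariate_effects = c(sex = 0, age = 0, tiv = 0))
  atlas <- generate_phantom_atlas(cfg0)
  cohort <- generate_cohort(cfg0)
  imgs <- generate_gm_images(cfg0, cohort, atlas)
  expect_equal(max(apply(imgs$data, 1, function(r) diff(range(r)))), 0)

  # planted group-level deficit (no causal refinement): realized
  # per-voxel Cohen's d near 0.8 at n = 60+60
  cfg <- sim_config(seed = 6, n_hc = 60, n_scz = 60, n_snps = 50,
                    affected_regions = 1, n_polygenic = 0,
                    causal_map = list())
  atlas <- generate_phantom_atlas(cfg)
  cohort <- generate_cohort(cfg)
  geno <- generate_genotypes(cfg, cohort)
  cohort <- plant_ba_phenotypes(cfg, cohort, geno)
  imgs <- generate_gm_images(cfg, cohort, atlas)
  grp <- cohort$subjects$group
  vox <- which(as.vector(atlas$grid) == 1)
  hc <- imgs$data[vox, grp == "HC"]
  scz <- imgs$data[vox, grp == "SCZ"]
  d_vox <- (rowMeans(hc) - rowMeans(scz)) /
    sqrt((apply(hc, 1, var) + apply(scz, 1, var)) / 2)
  expect_equal(mean(d_vox), 0.8, tolerance = 0.15)

  # grid mismatch rejected
  cfg_bad <- tiny_config(seed = 5, grid_shape = c(12, 12, 12))
  expect_error(generate_gm_images(cfg_bad, cohort, atlas),
               class = "areascan_invalid_input")
})

test_that("discovery summary statistics are calibrated and consistent", {
  cfg <- sim_config(seed = 8, n_hc = 30, n_scz = 30, n_snps = 2000,
                    n_polygenic = 100, dup_rate = 0.01)
  cohort <- generate_cohort(cfg)
  geno <- generate_genotypes(cfg, cohort)
  ss <- generate_discovery_sumstats(cfg, geno)

  # ~ dup_rate * n duplicates appended
  expect_equal(sum(duplicated(ss$SNP)), round(0.01 * 2000))

  # null SNPs: p < 0.05 at ~ 5%
  truth <- areascan:::polygenic_truth(cfg)
  nulls <- setdiff(seq_len(2000), truth$idx)
  frac <- mean(ss$P[nulls] < 0.05)
  se <- sqrt(0.05 * 0.95 / length(nulls))
  expect_lt(abs(frac - 0.05), 3 * se)

  # consistency: large discovery_n pulls betas to the planted truth
  cfg_big <- sim_config(seed = 8, n_hc = 30, n_scz = 30, n_snps = 2000,
                        n_polygenic = 100, discovery_n = 1e8, dup_rate = 0)
  ss_big <- generate_discovery_sumstats(cfg_big, geno)
  aligned_beta <- ifelse(ss_big$A1 == geno$snps$a1, ss_big$BETA, -ss_big$BETA)
  expect_equal(aligned_beta[truth$idx], truth$beta, tolerance = 1e-3)

  # determinism
  expect_identical(ss, generate_discovery_sumstats(cfg, geno))
})

test_that("expression fixtures are deterministic with exchangeable uniform genes", {
  cfg <- tiny_config(seed = 12)
  f1 <- generate_expression_fixtures(cfg)
  f2 <- generate_expression_fixtures(cfg)
  expect_identical(f1$expression$counts, f2$expression$counts)
  expect_identical(f1$ish, f2$ish)

  # the uniform gene (no preferred area): ratios equal across areas
  # within binomial error
  ratios <- positive_cell_ratio(f1$expression, "sg01")
  p <- mean(ratios)
  se <- sqrt(p * (1 - p) / cfg$expression$cells_per_area)
  expect_lt(max(abs(ratios - p)), 3.5 * se)

  # preferred-area genes have their maximum ratio in the designed area
  truth <- f1$design$sc_truth
  hits <- vapply(2:nrow(truth), function(i) {
    r <- positive_cell_ratio(f1$expression, truth$gene[i])
    colnames(r)[which.max(r)] == truth$preferred_area[i]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("generated fixtures survive write/read round trips", {
  cfg <- tiny_config(seed = 13, n_snps = 40)
  atlas <- generate_phantom_atlas(cfg)
  cohort <- generate_cohort(cfg)
  geno <- generate_genotypes(cfg, cohort)
  imgs <- generate_gm_images(cfg, cohort, atlas)
  ss <- generate_discovery_sumstats(cfg, geno)
  fx <- generate_expression_fixtures(cfg)
  td <- withr::local_tempdir()

  # cohort TSV
  p <- file.path(td, "cohort.tsv")
  write_cohort_tsv(cohort, p)
  back <- read_cohort_tsv(p)
  expect_equal(back$id, cohort$subjects$id)
  expect_equal(back$tiv, cohort$subjects$tiv)

  # label volume NIfTI + labels sidecar
  p <- file.path(td, "atlas.nii.gz")
  write_label_volume_nifti(atlas, p)
  back <- read_label_volume_nifti(p)
  expect_identical(back$grid, atlas$grid)
  expect_equal(back$voxel_size, atlas$voxel_size)
  expect_equal(back$labels, atlas$labels)

  # gray-matter images NIfTI
  d <- file.path(td, "gm")
  write_gm_images_nifti(imgs, d)
  back <- read_gm_images_nifti(d)
  expect_equal(back$subject_ids, sort(imgs$subject_ids))
  reord <- match(back$subject_ids, imgs$subject_ids)
  expect_equal(back$data, imgs$data[, reord], tolerance = 1e-6)

  # VCF round trip
  p <- file.path(td, "geno.vcf.gz")
  write_genotypes_vcf(geno, p)
  back <- read_genotypes_vcf(p)
  expect_identical(unname(back$dosage[geno$subject_ids, ]),
                   unname(geno$dosage))
  expect_equal(back$snps$bp, geno$snps$bp)
  expect_equal(back$snps$a1, geno$snps$a1)

  # dosage TSV round trip
  p <- file.path(td, "geno.tsv")
  write_dosage_tsv(geno, p)
  back <- read_dosage_tsv(p)
  expect_equal(unname(back$dosage), unname(geno$dosage))

  # summary stats TSV
  p <- file.path(td, "ss.tsv")
  write_sumstats_tsv(ss, p)
  back <- read_sumstats_tsv(p)
  expect_equal(back$BETA, ss$BETA)
  expect_equal(back$P, ss$P)

  # expression counts (TSV and MTX) + ISH
  for (ext in c("counts.tsv", "counts.mtx")) {
    cp <- file.path(td, ext)
    mp <- file.path(td, "meta.tsv")
    write_expression_matrix(fx$expression, cp, mp)
    back <- read_expression_matrix(cp, mp)
    expect_identical(unname(back$counts), unname(fx$expression$counts))
    expect_equal(back$cell_meta$area, fx$expression$cell_meta$area)
  }
  p <- file.path(td, "ish.tsv")
  write_ish_tsv(fx$ish, p)
  expect_equal(read_ish_tsv(p)$intensity, fx$ish$intensity)
})
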