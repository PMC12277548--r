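test_that("derive_ba_phenotype selects abnormally low volumes via the single-case test", {
  grp <- rep(c("HC", "SCZ"), c(100, 3))
  cohort <- make_cohort(grp, n_regions = 1)
  set.seed(71)
  hc_v <- rnorm(100, 50, 2)
  m <- mean(hc_v)
  s <- sd(hc_v)
  vols <- data.frame(id = cohort$subjects$id, region = 1,
                     volume_cm3 = c(hc_v, m, m - 3 * s, m - 1 * s))
  phen <- derive_ba_phenotype(vols, cohort, 1, alpha = 0.05)
  ids <- cohort$subjects$id[grp == "SCZ"]
  expect_false(ids[1] %in% phen$case_ids)  # at the HC mean
  expect_true(ids[2] %in% phen$case_ids)   # 3 SD below
  # 3-SD patient's p matches the single-case formula oracle
  t_or <- -3 * s / (s * sqrt(101 / 100))
  expect_equal(unname(phen$patient_p[ids[2]]), pt(t_or, 99), tolerance = 1e-10)
  expect_lt(phen$patient_p[ids[2]], 0.002)

  # alpha = 0 selects nobody
  expect_length(derive_ba_phenotype(vols, cohort, 1, alpha = 0)$case_ids, 0)
  expect_error(derive_ba_phenotype(vols, cohort, 2),
               class = "areascan_invalid_input")
})

test_that("qc_genotypes removes exactly the engineered violations, in order", {
  # 60 subjects; 6 SNPs: 1 low call rate, 1 low MAF, 1 HWE-violating,
  # 3 clean; plus one low-call-rate subject
  set.seed(72)
  n <- 60
  clean <- function() rbinom(n, 2, 0.3)
  dos <- cbind(clean(), clean(), clean(), clean(), clean(), clean())
  dos[1:10, 2] <- NA                      # SNP 2: call rate 50/60 < 0.95
  dos[, 4] <- c(1L, rep(0L, n - 1))       # SNP 4: MAF 1/120 < 0.01
  dos[, 6] <- rep(c(0L, 2L), n / 2)       # SNP 6: no hets, HWE exact tiny
  dos[60, c(1, 3, 5, 6)] <- NA            # subject 60: call rate 2/6
  geno <- make_genotypes(dos)
  res <- qc_genotypes(geno, snp_call_rate = 0.95, subject_call_rate = 0.5,
                      maf_min = 0.01, hwe_p = 1e-6)
  expect_equal(res$report$filter,
               c("snp_call_rate", "subject_call_rate", "maf", "hwe"))
  expect_equal(res$report$removed, c(1L, 1L, 1L, 1L))
  expect_setequal(colnames(res$genotypes$dosage),
                  c("rs0001", "rs0003", "rs0005"))
  expect_false("S0060" %in% rownames(res$genotypes$dosage))

  # clean matrix passes unchanged; extreme thresholds remove nothing
  geno_clean <- make_genotypes(cbind(clean(), clean()))
  res2 <- qc_genotypes(geno_clean)
  expect_identical(res2$genotypes$dosage, geno_clean$dosage)
  res3 <- qc_genotypes(geno, snp_call_rate = 0, subject_call_rate = 0,
                       maf_min = 0, hwe_p = 0)
  expect_identical(dim(res3$genotypes$dosage), dim(geno$dosage))
})

test_that("assoc_scan is allele-flip invariant and matches the saturated 2x2", {
  set.seed(73)
  n_case <- 60; n_ctrl <- 90
  dos <- cbind(rbinom(n_case + n_ctrl, 2, 0.4),
               rbinom(n_case + n_ctrl, 2, 0.25))
  geno <- make_genotypes(dos)
  ids <- geno$subject_ids
  phen <- make_phenotype(ids[1:n_case], ids[(n_case + 1):(n_case + n_ctrl)])
  tab <- assoc_scan(geno, phen, threshold = 5e-6)
  expect_equal(tab$STATUS, c("ok", "ok"))
  expect_equal(tab$OR, exp(tab$BETA))

  # flip: dosage g -> 2 - g
  geno_fl <- geno
  geno_fl$dosage <- 2L - geno$dosage
  tab_fl <- assoc_scan(geno_fl, phen, threshold = 5e-6)
  expect_equal(tab_fl$BETA, -tab$BETA, tolerance = 1e-9)
  expect_equal(tab_fl$OR, 1 / tab$OR, tolerance = 1e-9)
  expect_equal(tab_fl$P, tab$P, tolerance = 1e-9)

  # carrier-coded SNP reproduces the 2x2 cross-product ratio
  carrier <- c(rep(2L, 30), rep(0L, 30), rep(2L, 15), rep(0L, 75))
  geno2 <- make_genotypes(cbind(carrier))
  tab2 <- assoc_scan(geno2, phen)
  or_2x2 <- (30 * 75) / (30 * 15)
  expect_equal(exp(2 * tab2$BETA), or_2x2, tolerance = 1e-6)

  # monomorphic SNP is excluded, never significant
  geno3 <- make_genotypes(cbind(rep(1L, 150)))
  tab3 <- assoc_scan(geno3, phen)
  expect_true(tab3$STATUS %in% c("excluded_qc", "not_converged"))
  expect_false(tab3$SIGNIFICANT)

  expect_error(assoc_scan(geno, make_phenotype(character(0), ids)),
               class = "areascan_invalid_input")
})

test_that("shared_snp_table builds the indicator matrix from hand-built scans", {
  mk <- function(snps, sig) {
    data.frame(SNP = snps, SIGNIFICANT = sig, stringsAsFactors = FALSE)
  }
  per_region <- list(
    "13" = mk(c("rs1", "rs2", "rs3"), c(TRUE, TRUE, FALSE)),
    "23" = mk(c("rs1", "rs2", "rs3"), c(TRUE, FALSE, TRUE))
  )
  tab <- shared_snp_table(per_region)
  expect_equal(tab$SNP, c("rs1", "rs2", "rs3"))
  expect_equal(tab[["13"]], c(TRUE, TRUE, FALSE))
  expect_equal(tab[["23"]], c(TRUE, FALSE, TRUE))
  expect_equal(tab$n_regions, c(2, 1, 1))

  # SNP significant everywhere -> all TRUE row; empty input -> empty table
  all_sig <- shared_snp_table(list(a = mk("rs9", TRUE), b = mk("rs9", TRUE)))
  expect_true(all(unlist(all_sig[, c("a", "b")])))
  empty <- shared_snp_table(list(a = mk(character(0), logical(0))))
  expect_equal(nrow(empty), 0)
})

test_that("positional gene mapping honors windows and matches a brute-force scan", {
  ann <- data.frame(chrom = 1L, start = c(50000L, 200000L),
                    end = c(60000L, 230000L), name = c("GENE1", "GENE2"),
                    stringsAsFactors = FALSE)
  snps <- data.frame(SNP = c("in_body", "near", "far", "edge_in", "edge_out"),
                     CHR = 1L,
                     BP = c(55000L, 61000L, 300000L, 50000L - 9999L,
                            50000L - 10001L),
                     stringsAsFactors = FALSE)
  res <- map_snps_to_genes(snps, ann, window_kb = 10,
                           significant_only = FALSE)
  expect_true(all(c("in_body", "near", "edge_in") %in% res$mapped$SNP))
  expect_setequal(res$unmapped, c("far", "edge_out"))

  # window 0: only the SNP inside the gene body maps
  res0 <- map_snps_to_genes(snps, ann, window_kb = 0,
                            significant_only = FALSE)
  expect_equal(res0$mapped$SNP, "in_body")

  # random toy agrees with the brute-force interval scan
  set.seed(74)
  rsnps <- data.frame(SNP = sprintf("rs%d", 1:50), CHR = 1L,
                      BP = sample.int(500000L, 50), stringsAsFactors = FALSE)
  rann <- data.frame(chrom = 1L, start = sort(sample.int(450000L, 8)),
                     stringsAsFactors = FALSE)
  rann$end <- rann$start + sample.int(30000L, 8)
  rann$name <- sprintf("G%d", 1:8)
  ours <- map_snps_to_genes(rsnps, rann, window_kb = 5,
                            significant_only = FALSE)$mapped
  oracle <- interval_scan_oracle(rsnps, rann, 5000)
  key <- function(d) sort(paste(d$SNP, d$gene))
  expect_equal(key(ours), key(oracle))

  expect_error(map_snps_to_genes(snps, data.frame(chrom = 1, start = 10,
                                                  end = 5, name = "bad"),
                                 significant_only = FALSE),
               class = "areascan_invalid_input")
})

test_that("BED annotation is converted from 0-based half-open on read", {
  td <- withr::local_tempdir()
  bed <- file.path(td, "genes.bed")
  writeLines(c("chr1\t49999\t60000\tGENE1", "2\t100\t200\tGENE2"), bed)
  ann <- read_gene_annotation_bed(bed)
  expect_equal(ann$start, c(50000L, 101L))
  expect_equal(ann$end, c(60000L, 200L))
  expect_equal(ann$chrom, c(1L, 2L))
})

test_that("null-image phenotype derivation selects about alpha of patients", {
  cfg <- tiny_config(seed = 75, affected_regions = integer(0),
                     causal_map = list(), n_polygenic = 0,
                     n_hc = 40, n_scz = 40)
  atlas <- generate_phantom_atlas(cfg)
  cohort <- generate_cohort(cfg)
  imgs <- generate_gm_images(cfg, cohort, atlas)
  vols <- region_volume_table(imgs, atlas)
  rates <- vapply(seq_len(cfg$n_regions), function(r) {
    phen <- derive_ba_phenotype(vols, cohort, r, alpha = 0.05)
    length(phen$case_ids) / sum(cohort$subjects$group == "SCZ")
  }, numeric(1))
  n_trials <- cfg$n_regions * 40
  se <- sqrt(0.05 * 0.95 / n_trials)
  expect_lt(abs(mean(rates) - 0.05), 3 * se)
})
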