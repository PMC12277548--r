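# Simulation configuration and cohort generation.

#' Simulation configuration
#'
#' Assembles and validates the configuration driving every synthetic-data
#' generator. Defaults are desk-scale study conditions: a 32x32x32 grid
#' parcellated into 20 regions, 60 healthy controls (HC) and 60
#' schizophrenia (SCZ) subjects, 5,000 SNPs on one chromosome spaced
#' 10 kb apart, gray-matter deficits of standardized size `gm_effect_d`
#' planted in `affected_regions`, one causal SNP per affected region
#' driving per-region case status, and a polygenic architecture of
#' `n_polygenic` SNPs that tilts group membership and feeds the
#' discovery summary statistics.
#'
#' @param seed integer root seed; all generators derive substreams from it.
#' @param grid_shape three positive integers, the image grid.
#' @param n_regions number of parcels (>= 2).
#' @param n_hc,n_scz group sizes.
#' @param n_snps number of SNPs.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param affected_regions region labels receiving a gray-matter deficit.
#' @param causal_map named list, region label -> list(snp = index,
#'   effect = log odds ratio), the per-region causal SNPs. Defaults to
#'   one SNP of effect log(3) per affected region.
#' @param gm_effect_d standardized (Cohen's d) deficit per affected region.
#' @param noise_sd voxel noise standard deviation (gray-matter density
#'   units).
#' @param covariate_effects named numeric: slopes of sex, age (per year)
#'   and TIV (per cm^3) on voxel gray-matter density; nonzero by default
#'   so covariate adjustment is genuinely exercised.
#' @param missing_rate per-genotype missingness rate.
#' @param ld_flip_prob flip probability for copy-with-flip LD pairs
#'   (consecutive SNP pairs); dosage r^2 is (1-2*flip)^2 at maf 0.5 and
#'   analytically known elsewhere.
#' @param ld_pair_fraction fraction of SNPs paired into LD blocks.
#' @param n_polygenic number of polygenic causal SNPs.
#' @param polygenic_beta_range magnitude range of polygenic log odds
#'   ratios (signs random).
#' @param discovery_n effective discovery-study size; discovery beta
#'   noise and standard errors scale as 1/sqrt(discovery_n).
#' @param dup_rate,ambig_rate rates of duplicated and strand-ambiguous
#'   SNPs injected into the discovery summary statistics / SNP metadata.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param expression gene-expression fixture design; see
#'   [generate_expression_fixtures()].
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       grid_shape = c(32L, 32L, 32L),
                       n_regions = 20L,
                       n_hc = 60L,
                       n_scz = 60L,
                       n_snps = 5000L,
                       maf_range = c(0.05, 0.5),
                       affected_regions = 1:10,
                       causal_map = NULL,
                       gm_effect_d = 0.8,
                       noise_sd = 0.05,
                       covariate_effects = c(sex = 0.01, age = -5e-4,
                                             tiv = 5e-5),
                       missing_rate = 0.01,
                       ld_flip_prob = 0.05,
                       ld_pair_fraction = 0.1,
                       n_polygenic = 200L,
                       polygenic_beta_range = c(0.10, 0.15),
                       discovery_n = 2000L,
                       dup_rate = 0.002,
                       ambig_rate = 0.05,
                       voxel_size_mm = c(4, 4, 4),
                       expression = expression_design()) {
  cfg <- list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
              n_regions = as.integer(n_regions), n_hc = as.integer(n_hc),
              n_scz = as.integer(n_scz), n_snps = as.integer(n_snps),
              maf_range = maf_range, affected_regions = as.integer(affected_regions),
              causal_map = causal_map, gm_effect_d = gm_effect_d,
              noise_sd = noise_sd, covariate_effects = covariate_effects,
              missing_rate = missing_rate, ld_flip_prob = ld_flip_prob,
              ld_pair_fraction = ld_pair_fraction,
              n_polygenic = as.integer(n_polygenic),
              polygenic_beta_range = polygenic_beta_range,
              discovery_n = as.integer(discovery_n),
              dup_rate = dup_rate, ambig_rate = ambig_rate,
              voxel_size_mm = voxel_size_mm, expression = expression)
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 4))
    stop_config("grid_shape must be three integers >= 4")
  if (cfg$n_regions < 2) stop_config("need at least 2 regions")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop_config("maf_range must satisfy 0 < low <= high <= 0.5")
  if (any(!cfg$affected_regions %in% seq_len(cfg$n_regions)))
    stop_config("affected_regions outside 1..n_regions")
  if (is.null(cfg$causal_map)) {
    snps <- if (cfg$n_snps >= 10 * length(cfg$affected_regions))
      as.integer(seq(10, cfg$n_snps, length.out = max(1, length(cfg$affected_regions))))
    else seq_along(cfg$affected_regions)
    cfg$causal_map <- setNames(
      lapply(seq_along(cfg$affected_regions),
             function(i) list(snp = snps[i], effect = log(3))),
      as.character(cfg$affected_regions))
  }
  for (entry in cfg$causal_map) {
    if (entry$snp < 1 || entry$snp > cfg$n_snps)
      stop_config("causal_map SNP index out of range")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Study-scale configuration preset
#'
#' Returns a configuration at the size of the motivating cohort
#' (330 HC + 194 SCZ) with a larger SNP panel. Intended for
#' longer-running experiments; the package default is desk scale.
#'
#' @param seed root seed.
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_study_scale <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_hc = 330L, n_scz = 194L, n_snps = 50000L,
             discovery_n = 58140L, ...)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject demographics: sex (0/1, balanced), age (years,
#' normal around the early-forties mean typical of chronic-illness
#' cohorts), total intracranial volume (TIV, cm^3), MMSE (0-30, lower
#' and more variable in the SCZ group) and illness duration (years, SCZ
#' only). Group labels start as the first `n_hc` subjects HC and the
#' rest SCZ; [plant_ba_phenotypes()] may later reassign membership by
#' polygenic liability. Per-region case flags are initialized to "all
#' SCZ subjects affected in every affected region" (a pure group-level
#' deficit) and are refined to genotype-driven flags by
#' [plant_ba_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return an object of class `cohort`: a list with `subjects` (data
#'   frame id, group, sex, age, tiv, mmse, duration), `case_flags`
#'   (subjects x regions logical matrix) and `regions`.
#' @export
generate_cohort <- function(config) {
  set.seed(substream_seed(config$seed, "cohort"))
  n <- config$n_hc + config$n_scz
  group <- rep(c("HC", "SCZ"), c(config$n_hc, config$n_scz))
  subjects <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    group = group,
    sex = rbinom(n, 1, 0.5),
    age = round(pmin(80, pmax(20, rnorm(n, 43, 13))), 1),
    tiv = round(rnorm(n, 1450, 110), 1),
    stringsAsFactors = FALSE
  )
  subjects$mmse <- draw_mmse(group)
  subjects$duration <- draw_duration(group)
  flags <- outer(group == "SCZ",
                 seq_len(config$n_regions) %in% config$affected_regions, `&`)
  dimnames(flags) <- list(subjects$id, as.character(seq_len(config$n_regions)))
  structure(list(subjects = subjects, case_flags = flags,
                 regions = seq_len(config$n_regions)),
            class = "cohort")
}

draw_mmse <- function(group) {
  n <- length(group)
  mm <- ifelse(group == "HC", rnorm(n, 28.5, 1.2), rnorm(n, 26, 2.2))
  as.integer(pmin(30, pmax(0, round(mm))))
}

draw_duration <- function(group) {
  n <- length(group)
  dur <- round(pmax(0.5, rnorm(n, 15, 8)), 1)
  ifelse(group == "SCZ", dur, NA_real_)
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("cohort: %d subjects (%s), %d regions\n",
              nrow(x$subjects),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              length(x$regions)))
  invisible(x)
}

#' Write / read a cohort table
#'
#' @param cohort a `cohort`.
#' @param path TSV path.
#' @return `read_cohort_tsv` returns the subjects data frame.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write_tsv_schema(cohort$subjects, path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) read_tsv_checked(path)

#' Rebuild a cohort object from a subjects table
#'
#' Reconstructs the `cohort` container from a subjects data frame (as
#' read by [read_cohort_tsv()]). Per-region case flags are initialized
#' to FALSE (they are an analysis-internal construct; phenotype
#' derivation recomputes caseness from volumes).
#'
#' @param subjects data frame with id, group, sex, age, tiv, mmse,
#'   duration.
#' @param n_regions number of regions.
#' @return a `cohort`.
#' @export
cohort_from_table <- function(subjects, n_regions) {
  need <- c("id", "group", "sex", "age", "tiv")
  if (!all(need %in% names(subjects)))
    stop_invalid("subjects table needs columns %s",
                 paste(need, collapse = ", "))
  flags <- matrix(FALSE, nrow(subjects), n_regions,
                  dimnames = list(subjects$id,
                                  as.character(seq_len(n_regions))))
  structure(list(subjects = as.data.frame(subjects), case_flags = flags,
                 regions = seq_len(n_regions)),
            class = "cohort")
}
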