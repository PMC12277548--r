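# Shared fixture builders (all generated in code at test time).

# small configuration for fast end-to-end tests
tiny_config <- function(seed = 1L, ...) {
  args <- modifyList(list(seed = seed, grid_shape = c(16L, 16L, 16L),
                          n_regions = 5L, n_hc = 20L, n_scz = 20L,
                          n_snps = 200L, affected_regions = 1:2,
                          n_polygenic = 40L),
                     list(...))
  do.call(sim_config, args)
}

# hand-built genotype matrix from a dosage matrix
make_genotypes <- function(dosage, bp = NULL, a1 = NULL, a2 = NULL,
                           chr = 1L) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(bp)) bp <- 10000L * seq_len(m)
  if (is.null(a1)) a1 <- rep("G", m)
  if (is.null(a2)) a2 <- rep("A", m)
  snps <- data.frame(snp = sprintf("rs%04d", seq_len(m)), chr = chr,
                     bp = bp, a1 = a1, a2 = a2,
                     maf = pmin(colMeans(dosage, na.rm = TRUE) / 2,
                                1 - colMeans(dosage, na.rm = TRUE) / 2),
                     stringsAsFactors = FALSE)
  ids <- sprintf("S%04d", seq_len(n))
  dimnames(dosage) <- list(ids, snps$snp)
  structure(list(dosage = dosage, snps = snps, subject_ids = ids),
            class = "genotype_matrix")
}

# phenotype assignment built directly (bypassing volume derivation)
make_phenotype <- function(case_ids, control_ids, region = 1L) {
  structure(list(region = region, case_ids = case_ids,
                 control_ids = control_ids,
                 patient_p = setNames(rep(NA_real_, length(case_ids)),
                                      case_ids),
                 alpha = 0.05),
            class = "phenotype_assignment")
}

# minimal cohort from a group vector
make_cohort <- function(group, n_regions = 3L, seed = 1L) {
  set.seed(seed)
  n <- length(group)
  subjects <- data.frame(id = sprintf("S%04d", seq_len(n)), group = group,
                         sex = rbinom(n, 1, 0.5),
                         age = round(runif(n, 20, 70), 1),
                         tiv = round(rnorm(n, 1450, 100), 1),
                         stringsAsFactors = FALSE)
  subjects$mmse <- 28L
  subjects$duration <- ifelse(group == "SCZ", 10, NA_real_)
  flags <- matrix(FALSE, n, n_regions,
                  dimnames = list(subjects$id, as.character(seq_len(n_regions))))
  structure(list(subjects = subjects, case_flags = flags,
                 regions = seq_len(n_regions)),
            class = "cohort")
}

# summary stats table from components
make_sumstats <- function(snp, bp, beta, p, a1 = "G", a2 = "A",
                          chr = 1L, se = 0.1) {
  df <- data.frame(SNP = snp, CHR = chr, BP = bp, A1 = a1, A2 = a2,
                   BETA = beta, SE = se, P = p, stringsAsFactors = FALSE)
  class(df) <- c("summary_stats", "data.frame")
  df
}
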