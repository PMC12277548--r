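# Genotype, case-status and discovery summary-statistic generators.

#' Generate Hardy-Weinberg genotypes with optional LD pairs
#'
#' Per SNP, a minor-allele frequency is drawn uniformly from the
#' configured range and genotypes are drawn Binomial(2, maf)
#' independently per subject, so Hardy-Weinberg equilibrium holds by
#' construction. A configurable fraction of SNPs is paired into LD
#' blocks by copy-with-flip at the haplotype level: the paired SNP
#' copies each of its neighbor's two allele copies, flipping each with
#' probability `ld_flip_prob`, giving an analytically known dosage
#' r^2 ((1 - 2 flip)^2 when the minor-allele frequency is 0.5).
#' Missing genotypes are injected at `missing_rate`. SNP metadata
#' (rsid, chromosome, position, alleles) is synthesized on one
#' chromosome with positions 10 kb apart; strand-ambiguous allele pairs
#' (A/T, C/G) occur at `ambig_rate`.
#'
#' @param config a [sim_config()].
#' @param cohort a [generate_cohort()] cohort (defines subjects).
#' @return an object of class `genotype_matrix`: list with `dosage`
#'   (subjects x SNPs integer matrix, NA = missing; counts of the `a1`
#'   allele), `snps` (data frame snp, chr, bp, a1, a2, maf) and
#'   `subject_ids`.
#' @export
generate_genotypes <- function(config, cohort) {
  set.seed(substream_seed(config$seed, "genotypes"))
  n <- nrow(cohort$subjects)
  m <- config$n_snps
  if (m < 1) stop_config("need at least 1 SNP")
  maf <- runif(m, config$maf_range[1], config$maf_range[2])

  # haplotypes drawn per subject so LD pairs can copy-with-flip
  h1 <- matrix(rbinom(n * m, 1, rep(maf, each = n)), n, m)
  h2 <- matrix(rbinom(n * m, 1, rep(maf, each = n)), n, m)

  n_pairs <- floor(config$ld_pair_fraction * m / 2)
  if (n_pairs > 0) {
    parents <- seq(1, by = 2, length.out = n_pairs)
    for (i in parents) {
      j <- i + 1
      flip1 <- rbinom(n, 1, config$ld_flip_prob)
      flip2 <- rbinom(n, 1, config$ld_flip_prob)
      h1[, j] <- ifelse(flip1 == 1, 1 - h1[, i], h1[, i])
      h2[, j] <- ifelse(flip2 == 1, 1 - h2[, i], h2[, i])
      maf[j] <- maf[i] * (1 - config$ld_flip_prob) +
        (1 - maf[i]) * config$ld_flip_prob
    }
  }
  dosage <- h1 + h2
  storage.mode(dosage) <- "integer"
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * m) < config$missing_rate, n, m)
    dosage[miss] <- NA_integer_
  }
  ambig <- runif(m) < config$ambig_rate
  pairs_plain <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                      c("A", "C"), c("G", "T"))
  pairs_ambig <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pick <- function(amb) {
    if (amb) pairs_ambig[[sample.int(4, 1)]] else pairs_plain[[sample.int(6, 1)]]
  }
  alleles <- t(vapply(ambig, pick, character(2)))
  snps <- data.frame(snp = sprintf("rs%06d", seq_len(m)),
                     chr = 1L,
                     bp = 10000L * seq_len(m),
                     a1 = alleles[, 1],
                     a2 = alleles[, 2],
                     maf = maf,
                     stringsAsFactors = FALSE)
  dimnames(dosage) <- list(cohort$subjects$id, snps$snp)
  structure(list(dosage = dosage, snps = snps,
                 subject_ids = cohort$subjects$id),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

# the polygenic architecture (causal SNP indices and true log odds
# ratios) is a pure function of the configuration, so the cohort
# assignment and the discovery summary statistics see the same truth
polygenic_truth <- function(config) {
  set.seed(substream_seed(config$seed, "polygenic_truth"))
  m <- config$n_snps
  k <- min(config$n_polygenic, m)
  idx <- sort(sample.int(m, k))
  mag <- runif(k, config$polygenic_beta_range[1], config$polygenic_beta_range[2])
  sign <- sample(c(-1, 1), k, replace = TRUE)
  list(idx = idx, beta = mag * sign)
}

# mean-imputed dosage (per SNP) for score computations
impute_dosage <- function(dosage) {
  means <- colMeans(dosage, na.rm = TRUE)
  means[is.nan(means)] <- 0
  na_idx <- which(is.na(dosage))
  if (length(na_idx)) {
    dosage[na_idx] <- means[((na_idx - 1) %/% nrow(dosage)) + 1]
  }
  dosage
}

#' Plant genetic structure into the cohort
#'
#' Two causal layers are planted. First, group membership (HC vs SCZ) is
#' tilted by the polygenic liability: each subject's liability is the
#' dosage-weighted sum of the polygenic true effects, and the configured
#' number of SCZ subjects is drawn without replacement with weights
#' proportional to exp(liability) (retrospective case-control
#' enrichment); group-dependent covariates (MMSE, illness duration) are
#' re-drawn under the new labels. Second, for each region in
#' `causal_map`, per-subject case probability is
#' logistic(intercept + effect x dosage) at that region's causal SNP,
#' with the intercept set so the mean case probability is about 0.6;
#' SCZ subjects are sampled as region cases accordingly and HC subjects
#' are never cases. Affected regions without a causal entry keep the
#' group-level flag (all SCZ affected).
#'
#' @param config a [sim_config()].
#' @param cohort a [generate_cohort()] cohort.
#' @param genotypes a [generate_genotypes()] matrix.
#' @return the cohort with reassigned groups and filled per-region case
#'   flags; realized per-region case counts are attached as attribute
#'   `case_counts`, and regions whose case set came out empty are listed
#'   in attribute `empty_regions` (with a warning).
#' @export
plant_ba_phenotypes <- function(config, cohort, genotypes) {
  set.seed(substream_seed(config$seed, "plant"))
  for (entry in config$causal_map) {
    if (entry$snp < 1 || entry$snp > ncol(genotypes$dosage))
      stop_invalid("causal_map SNP index %d out of range", entry$snp)
  }
  dos <- impute_dosage(genotypes$dosage)
  n <- nrow(cohort$subjects)

  # polygenic tilt of group membership
  if (config$n_polygenic > 0) {
    truth <- polygenic_truth(config)
    liability <- drop(dos[, truth$idx, drop = FALSE] %*% truth$beta)
    w <- exp(liability - max(liability))
    scz_idx <- sample.int(n, config$n_scz, prob = w)
    group <- rep("HC", n)
    group[scz_idx] <- "SCZ"
    cohort$subjects$group <- group
    cohort$subjects$mmse <- draw_mmse(group)
    cohort$subjects$duration <- draw_duration(group)
  }
  is_scz <- cohort$subjects$group == "SCZ"

  # reset flags to the group-level default, then refine causal regions
  flags <- outer(is_scz,
                 cohort$regions %in% config$affected_regions, `&`)
  dimnames(flags) <- list(cohort$subjects$id, as.character(cohort$regions))
  counts <- integer(0)
  empty <- character(0)
  for (rname in names(config$causal_map)) {
    entry <- config$causal_map[[rname]]
    g <- dos[, entry$snp]
    intercept <- stats::qlogis(0.6) - entry$effect * mean(g)
    p_case <- plogis(intercept + entry$effect * g)
    case <- is_scz & (runif(n) < p_case)
    flags[, rname] <- case
    counts[rname] <- sum(case)
    if (sum(case) == 0) empty <- c(empty, rname)
  }
  if (length(empty)) {
    warning(sprintf("no cases realized for region(s): %s",
                    paste(empty, collapse = ", ")))
  }
  cohort$case_flags <- flags
  attr(cohort, "case_counts") <- counts
  attr(cohort, "empty_regions") <- empty
  cohort
}

#' Generate a synthetic gene annotation
#'
#' Tiles the simulated chromosome with gene intervals (1-based
#' inclusive) of varying length separated by intergenic gaps, for
#' positional SNP-to-gene mapping. Synthetic gene names are
#' `sgene0001`, ...
#'
#' @param config a [sim_config()].
#' @param mean_gene_bp,mean_gap_bp mean gene and gap lengths (bp).
#' @return data frame with chrom, start, end, name.
#' @export
generate_gene_annotation <- function(config, mean_gene_bp = 40000,
                                     mean_gap_bp = 60000) {
  set.seed(substream_seed(config$seed, "annotation"))
  chrom_end <- 10000 * config$n_snps + 10000
  rows <- list()
  pos <- 1
  k <- 0
  while (pos < chrom_end) {
    gap <- round(stats::rexp(1, 1 / mean_gap_bp))
    len <- max(1000, round(stats::rexp(1, 1 / mean_gene_bp)))
    start <- pos + gap
    if (start >= chrom_end) break
    k <- k + 1
    rows[[k]] <- data.frame(chrom = 1L, start = start,
                            end = min(start + len, chrom_end),
                            name = sprintf("sgene%04d", k),
                            stringsAsFactors = FALSE)
    pos <- start + len + 1
  }
  do.call(rbind, rows)
}

#' Generate noisy discovery summary statistics
#'
#' Emulates a discovery GWAS over the same SNP panel: the reported beta
#' is the true planted polygenic effect plus Gaussian noise of scale
#' 1/sqrt(discovery_n), the standard error is that scale, and the
#' p-value is the two-sided Wald p. To exercise downstream PRS quality
#' control, a fraction of rows has its effect/other alleles swapped
#' (with the beta sign flipped, so the record is correct but needs
#' alignment), and duplicate rows are appended at `dup_rate`.
#' Strand-ambiguous SNPs are already present in the panel metadata.
#'
#' @param config a [sim_config()].
#' @param genotypes a [generate_genotypes()] matrix.
#' @param swap_fraction fraction of rows emitted with swapped alleles.
#' @return a `summary_stats` data frame with columns SNP, CHR, BP, A1
#'   (effect allele), A2, BETA, SE, P.
#' @export
generate_discovery_sumstats <- function(config, genotypes,
                                        swap_fraction = 0.2) {
  set.seed(substream_seed(config$seed, "sumstats"))
  m <- config$n_snps
  beta_true <- rep(0, m)
  if (config$n_polygenic > 0) {
    truth <- polygenic_truth(config)
    beta_true[truth$idx] <- truth$beta
  }
  se <- 1 / sqrt(config$discovery_n)
  beta_hat <- beta_true + rnorm(m, 0, se)
  p <- 2 * pnorm(-abs(beta_hat) / se)
  stats <- data.frame(SNP = genotypes$snps$snp,
                      CHR = genotypes$snps$chr,
                      BP = genotypes$snps$bp,
                      A1 = genotypes$snps$a1,
                      A2 = genotypes$snps$a2,
                      BETA = beta_hat,
                      SE = se,
                      P = pmax(p, .Machine$double.xmin),
                      stringsAsFactors = FALSE)
  swap <- runif(m) < swap_fraction
  tmp <- stats$A1[swap]
  stats$A1[swap] <- stats$A2[swap]
  stats$A2[swap] <- tmp
  stats$BETA[swap] <- -stats$BETA[swap]
  n_dup <- round(config$dup_rate * m)
  if (n_dup > 0) {
    dup_rows <- stats[sample.int(m, n_dup), , drop = FALSE]
    stats <- rbind(stats, dup_rows)
  }
  class(stats) <- c("summary_stats", "data.frame")
  stats
}
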