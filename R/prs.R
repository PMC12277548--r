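# Clumping-and-thresholding polygenic risk scoring.

PRS_DEFAULT_GRID <- c(5e-8, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05,
                      0.1, 0.2, 0.3, 0.4, 0.5, 1)

#' Prepare discovery summary statistics against a target panel
#'
#' Quality control and allele alignment: drops duplicated rsids (keeps
#' the first occurrence), strand-ambiguous SNPs (A/T, C/G), and SNPs
#' absent from the target panel; aligns the effect allele to the
#' target's counted allele, negating the beta when the alleles are
#' swapped, and drops SNPs whose alleles cannot be reconciled with the
#' target's.
#'
#' @param stats summary-stats data frame (SNP, CHR, BP, A1, A2, BETA,
#'   SE, P); A1 is the effect allele.
#' @param genotypes target `genotype_matrix` (counted allele = `a1`).
#' @return the filtered, aligned summary stats; a `qc_log` attribute
#'   records counts removed per step.
#' @export
prepare_sumstats <- function(stats, genotypes) {
  log <- c()
  dup <- duplicated(stats$SNP)
  log["duplicates"] <- sum(dup)
  stats <- stats[!dup, , drop = FALSE]

  ambig <- (stats$A1 == "A" & stats$A2 == "T") |
    (stats$A1 == "T" & stats$A2 == "A") |
    (stats$A1 == "C" & stats$A2 == "G") |
    (stats$A1 == "G" & stats$A2 == "C")
  log["ambiguous"] <- sum(ambig)
  stats <- stats[!ambig, , drop = FALSE]

  idx <- match(stats$SNP, genotypes$snps$snp)
  log["absent_from_target"] <- sum(is.na(idx))
  stats <- stats[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]

  t_a1 <- genotypes$snps$a1[idx]
  t_a2 <- genotypes$snps$a2[idx]
  same <- stats$A1 == t_a1 & stats$A2 == t_a2
  swapped <- stats$A1 == t_a2 & stats$A2 == t_a1
  log["allele_mismatch"] <- sum(!same & !swapped)
  stats$BETA[swapped] <- -stats$BETA[swapped]
  tmp <- stats$A1[swapped]
  stats$A1[swapped] <- stats$A2[swapped]
  stats$A2[swapped] <- tmp
  stats <- stats[same | swapped, , drop = FALSE]
  if (nrow(stats) == 0) stop_invalid("no summary-stats SNPs overlap the target")
  rownames(stats) <- NULL
  attr(stats, "qc_log") <- log
  stats
}

#' Greedy LD clumping
#'
#' Visits SNPs by ascending discovery p (ties by ascending position)
#' and keeps a SNP as an index unless the squared Pearson correlation
#' of its dosages with an already-kept index within the window exceeds
#' the threshold. The target genotypes serve as the LD reference.
#'
#' @param stats prepared summary stats (see [prepare_sumstats()]).
#' @param genotypes target `genotype_matrix`.
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @param window_kb clumping window in kb (default 250).
#' @return the subset of `stats` rows kept as index SNPs (original
#'   order by ascending p).
#' @export
ld_clump <- function(stats, genotypes, r2_threshold = 0.1, window_kb = 250) {
  idx <- match(stats$SNP, genotypes$snps$snp)
  if (any(is.na(idx))) stop_invalid("genotypes do not cover the stats SNPs")
  dos <- impute_dosage(genotypes$dosage[, idx, drop = FALSE])
  ord <- order(stats$P, stats$BP)
  w <- window_kb * 1000
  kept <- integer(0)
  for (i in ord) {
    near <- kept[stats$CHR[kept] == stats$CHR[i] &
                   abs(stats$BP[kept] - stats$BP[i]) <= w]
    ok <- TRUE
    for (j in near) {
      if (sd(dos[, i]) == 0 || sd(dos[, j]) == 0) next
      if (cor(dos[, i], dos[, j])^2 > r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- stats[sort(kept), , drop = FALSE]
  out[order(out$P, out$BP), , drop = FALSE]
}

#' Polygenic score at one p-value threshold
#'
#' score(subject) = sum over SNPs with discovery p <= threshold of
#' beta times the effect-allele dosage; missing dosages contribute the
#' effect-allele frequency (mean imputation, as in standard scoring
#' tools).
#'
#' @param genotypes target `genotype_matrix`.
#' @param stats prepared summary stats.
#' @param threshold p-value threshold.
#' @param ids subjects to score (default all genotype rows).
#' @return named numeric vector of raw scores.
#' @export
prs_score <- function(genotypes, stats, threshold, ids = NULL) {
  if (is.null(ids)) ids <- rownames(genotypes$dosage)
  idx <- match(stats$SNP, genotypes$snps$snp)
  if (any(is.na(idx))) stop_invalid("genotypes do not cover the stats SNPs")
  dos <- impute_dosage(genotypes$dosage[ids, idx, drop = FALSE])
  use <- which(stats$P <= threshold)
  if (!length(use)) return(setNames(rep(0, length(ids)), ids))
  setNames(drop(dos[, use, drop = FALSE] %*% stats$BETA[use]), ids)
}

#' Polygenic score threshold scan
#'
#' For each p-value threshold T in the grid, scores every subject as
#' the sum over SNPs with discovery p <= T of beta times the dosage of
#' the effect allele (missing dosages contribute the effect-allele
#' frequency), fits case status on the score by logistic regression,
#' and records the Nagelkerke pseudo-R-squared. The best threshold
#' maximizes R-squared (ties to the smaller threshold); scores at the
#' best threshold are z-standardized over all subjects.
#'
#' @param genotypes target `genotype_matrix`.
#' @param stats clumped, prepared summary stats.
#' @param y named binary phenotype vector (1 = SCZ/case), names =
#'   subject ids covering the genotype rows.
#' @param grid p-value threshold grid (default PRSice-like, 5e-8..1).
#' @return an object of class `prs_result`: list with `scan` (data
#'   frame threshold, n_snps, r2, converged), `best_threshold`,
#'   `raw_scores`, `scores` (standardized), `degenerate` flag.
#' @export
prs_scan <- function(genotypes, stats, y, grid = PRS_DEFAULT_GRID) {
  if (length(grid) == 0) stop_invalid("threshold grid must be non-empty")
  grid <- sort(grid)
  ids <- rownames(genotypes$dosage)
  if (!all(names(y) %in% ids)) stop_invalid("phenotype names missing from genotypes")
  y <- y[ids[ids %in% names(y)]]
  if (length(unique(y)) < 2) stop_invalid("phenotype must have both classes")
  n <- length(y)
  ll0 <- null_loglik(y)

  scan <- data.frame(threshold = grid, n_snps = NA_integer_,
                     r2 = NA_real_, converged = NA)
  scores_by_t <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    scan$n_snps[k] <- sum(stats$P <= grid[k])
    score <- unname(prs_score(genotypes, stats, grid[k], ids = names(y)))
    scores_by_t[[k]] <- score
    if (sd(score) == 0) {
      scan$r2[k] <- 0
      scan$converged[k] <- TRUE
      next
    }
    fit <- logistic_fit(y, cbind(1, score))
    if (!fit$converged) {
      warning(sprintf("non-convergent fit at threshold %g; skipped", grid[k]))
      scan$converged[k] <- FALSE
      next
    }
    scan$converged[k] <- TRUE
    scan$r2[k] <- nagelkerke_r2(ll0, fit$log_likelihood, n)
  }
  usable <- which(!is.na(scan$r2))
  if (!length(usable)) stop_invalid("no threshold produced a usable fit")
  best <- usable[which.max(scan$r2[usable])]  # ties: smaller threshold wins
  raw <- scores_by_t[[best]]
  degenerate <- sd(raw) == 0
  std <- if (degenerate) rep(0, n) else (raw - mean(raw)) / sd(raw)
  structure(list(scan = scan, best_threshold = grid[best],
                 best_r2 = scan$r2[best],
                 raw_scores = setNames(raw, names(y)),
                 scores = setNames(std, names(y)),
                 y = y, degenerate = degenerate),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("PRS scan: best threshold %g (R2 = %.4f, %d SNPs)%s\n",
              x$best_threshold, x$best_r2,
              x$scan$n_snps[x$scan$threshold == x$best_threshold],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Compare standardized polygenic scores between groups
#'
#' Welch two-sample test of the standardized scores between the two
#' groups (HC vs SCZ).
#'
#' @param result a `prs_result`.
#' @param groups named character vector (subject id -> "HC"/"SCZ");
#'   defaults to the phenotype the scan was fitted on.
#' @return a [test_result].
#' @export
compare_groups <- function(result, groups = NULL) {
  s <- result$scores
  if (is.null(groups)) {
    lab <- ifelse(result$y[names(s)] == 1, "SCZ", "HC")
  } else {
    lab <- groups[names(s)]
  }
  g1 <- s[lab == "SCZ"]
  g0 <- s[lab == "HC"]
  if (length(g1) == 0 || length(g0) == 0) stop_invalid("one group is empty")
  if (sd(g1) == 0 && sd(g0) == 0) stop_degenerate("constant scores in both groups")
  welch_t(g1, g0)
}

#' Write PRS results as TSVs
#'
#' `<prefix>_scan.tsv` holds the per-threshold scan;
#' `<prefix>_scores.tsv` the per-subject raw and standardized scores
#' (histogram-ready).
#'
#' @param result a `prs_result`.
#' @param prefix output path prefix.
#' @export
write_prs_tsv <- function(result, prefix) {
  write_tsv_schema(result$scan, paste0(prefix, "_scan.tsv"))
  scores <- data.frame(id = names(result$scores),
                       group = ifelse(result$y == 1, "SCZ", "HC"),
                       raw_score = unname(result$raw_scores),
                       std_score = unname(result$scores),
                       stringsAsFactors = FALSE)
  write_tsv_schema(scores, paste0(prefix, "_scores.tsv"))
  invisible(prefix)
}
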