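test_that("prepare_sumstats drops duplicates, ambiguous and absent SNPs and aligns alleles", {
  set.seed(81)
  dos <- matrix(rbinom(20 * 5, 2, 0.3), 20, 5)
  geno <- make_genotypes(dos, a1 = c("G", "G", "G", "G", "C"),
                         a2 = c("A", "A", "A", "A", "T"))
  # 8 rows: 2 duplicates of rs0001, 2 ambiguous, 1 absent, 3 usable
  ss <- make_sumstats(
    snp = c("rs0001", "rs0001", "rs0002", "rs0003", "rs0004", "rs9999",
            "rs0005", "rs0005b"),
    bp = c(10000, 10000, 20000, 30000, 40000, 99000, 50000, 51000),
    beta = c(0.5, 0.5, 0.3, -0.2, 0.1, 0.4, 0.2, 0.2),
    p = rep(0.01, 8),
    a1 = c("G", "G", "A", "G", "A", "G", "C", "G"),
    a2 = c("A", "A", "T", "A", "G", "A", "T", "A"))
  # rs0002: A/T ambiguous; rs0005b & rs0005 pair: rs0005 has C/T in
  # stats but target is C/T -> fine; rs0005b absent
  prepared <- prepare_sumstats(ss, geno)
  log <- attr(prepared, "qc_log")
  expect_equal(unname(log["duplicates"]), 1)
  expect_equal(unname(log["ambiguous"]), 1)
  expect_equal(unname(log["absent_from_target"]), 2)  # rs9999 + rs0005b
  expect_setequal(prepared$SNP, c("rs0001", "rs0003", "rs0004", "rs0005"))

  # rs0004: stats effect allele A = target's other allele -> beta negated
  expect_equal(prepared$BETA[prepared$SNP == "rs0004"], -0.1)
  expect_equal(prepared$A1[prepared$SNP == "rs0004"], "G")
  # rs0001 alleles already aligned -> untouched
  expect_equal(prepared$BETA[prepared$SNP == "rs0001"], 0.5)

  # zero overlap errors
  none <- make_sumstats("rsX", 1, 0.1, 0.5)
  expect_error(prepare_sumstats(none, geno), class = "areascan_invalid_input")
})

test_that("ld_clump keeps the lowest-p SNP among correlated neighbors", {
  set.seed(82)
  base <- rbinom(100, 2, 0.4)
  other <- rbinom(100, 2, 0.4)
  indep <- matrix(rbinom(100 * 2, 2, 0.4), 100, 2)
  # SNP1 and SNP2 identical dosages, 50 kb apart; SNP3/SNP4 independent
  dos <- cbind(base, base, indep)
  geno <- make_genotypes(dos, bp = c(100000L, 150000L, 500000L, 900000L))
  ss <- make_sumstats(geno$snps$snp, geno$snps$bp,
                      beta = c(0.5, 0.4, 0.2, 0.1),
                      p = c(1e-8, 1e-4, 0.01, 0.2))
  kept <- ld_clump(ss, geno, r2_threshold = 0.1, window_kb = 250)
  expect_setequal(kept$SNP, c("rs0001", "rs0003", "rs0004"))

  # same identical pair beyond the window: both kept
  geno_far <- make_genotypes(dos, bp = c(100000L, 400001L, 500000L, 900000L))
  ss_far <- make_sumstats(geno_far$snps$snp, geno_far$snps$bp,
                          beta = c(0.5, 0.4, 0.2, 0.1),
                          p = c(1e-8, 1e-4, 0.01, 0.2))
  kept_far <- ld_clump(ss_far, geno_far, r2_threshold = 0.1, window_kb = 250)
  expect_equal(nrow(kept_far), 4)

  # mutually uncorrelated SNPs all kept; a single SNP is kept
  solo <- ld_clump(ss[1, ], geno, r2_threshold = 0.1)
  expect_equal(nrow(solo), 1)
})

test_that("prs_scan reproduces hand-computed scores and selects thresholds correctly", {
  # 2 subjects x 2 SNPs, betas {0.5, -0.2}, hand-listed dosages
  dos <- matrix(c(2L, 1L,
                  0L, 2L), 2, 2)
  geno <- make_genotypes(dos, bp = c(10000L, 500000L))
  ss <- make_sumstats(geno$snps$snp, geno$snps$bp, beta = c(0.5, -0.2),
                      p = c(1e-6, 1e-3))
  # at T=1e-6 only SNP1: scores (0.5*2, 0.5*1) = (1.0, 0.5)
  # at T=1e-2 both:      (1.0 + 0, 0.5 - 0.4) = (1.0, 0.1)
  expect_equal(unname(prs_score(geno, ss, 1e-6)), c(1.0, 0.5))
  expect_equal(unname(prs_score(geno, ss, 1e-2)), c(1.0, 0.1))
  expect_equal(unname(prs_score(geno, ss, 1e-9)), c(0, 0))

  # scan on a convergent fixture: 12 subjects with the same 2 SNPs
  set.seed(85)
  dos12 <- matrix(rbinom(24, 2, 0.4), 12, 2)
  geno12 <- make_genotypes(dos12, bp = c(10000L, 500000L))
  ss12 <- make_sumstats(geno12$snps$snp, geno12$snps$bp,
                        beta = c(0.5, -0.2), p = c(1e-6, 1e-3))
  y <- setNames(rep(c(1, 0), 6), geno12$subject_ids)
  res <- prs_scan(geno12, ss12, y, grid = c(1e-6, 1e-2))
  expect_equal(res$scan$n_snps, c(1, 2))
  expect_equal(mean(res$scores), 0, tolerance = 1e-9)
  expect_equal(sd(res$scores), 1, tolerance = 1e-9)

  # single-threshold grid: that threshold is best
  res1 <- prs_scan(geno12, ss12, y, grid = 0.5)
  expect_equal(res1$best_threshold, 0.5)

  # all betas zero: degenerate flag, zero R2
  ss0 <- make_sumstats(geno12$snps$snp, geno12$snps$bp, beta = c(0, 0),
                       p = c(1e-6, 1e-3))
  res0 <- prs_scan(geno12, ss0, y, grid = c(1e-6, 1))
  expect_true(res0$degenerate)
  expect_equal(res0$best_r2, 0)
})

test_that("prs_scan Nagelkerke R2 matches glm on a larger fixture and scoring is linear", {
  set.seed(83)
  n <- 60
  dos <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
  geno <- make_genotypes(dos)
  beta <- rnorm(8, 0, 0.4)
  ss <- make_sumstats(geno$snps$snp, geno$snps$bp, beta = beta,
                      p = runif(8, 1e-6, 0.4))
  score_true <- drop(dos %*% beta)
  y <- setNames(rbinom(n, 1, plogis(score_true - mean(score_true))),
                geno$subject_ids)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  res <- prs_scan(geno, ss, y, grid = c(0.05, 0.5, 1))

  # independent likelihood-ratio evaluation of the best threshold's R2
  use <- ss$P <= res$best_threshold
  s <- drop(dos[, use, drop = FALSE] %*% beta[use])
  fit <- glm(y ~ s, family = binomial())
  null <- glm(y ~ 1, family = binomial())
  oracle <- (1 - exp((2 / n) * (logLik(null)[1] - logLik(fit)[1]))) /
    (1 - exp((2 / n) * logLik(null)[1]))
  expect_equal(res$best_r2, oracle, tolerance = 1e-8)

  # linearity: scaling betas scales raw scores, leaves R2 and
  # standardized scores unchanged
  ss_scaled <- ss
  ss_scaled$BETA <- 3 * ss$BETA
  res_s <- prs_scan(geno, ss_scaled, y, grid = c(0.05, 0.5, 1))
  expect_equal(res_s$raw_scores, 3 * res$raw_scores, tolerance = 1e-9)
  expect_equal(res_s$scores, res$scores, tolerance = 1e-9)
  expect_equal(res_s$scan$r2, res$scan$r2, tolerance = 1e-9)
})

test_that("best threshold lands in the designed band when discovery p separates", {
  hits <- vapply(1:5, function(seed) {
    set.seed(900 + seed)
    n <- 120
    m <- 300
    n_causal <- 40
    dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
    geno <- make_genotypes(dos)
    beta_true <- c(rnorm(n_causal, 0, 0.25), rep(0, m - n_causal))
    # causal discovery p placed in [1e-6, 1e-4), nulls at >= 1e-2
    p <- c(10^runif(n_causal, -6, -4.0001), 10^runif(m - n_causal, -2, 0))
    ss <- make_sumstats(geno$snps$snp, geno$snps$bp, beta = beta_true, p = p)
    lia <- drop(dos %*% beta_true)
    y <- setNames(rbinom(n, 1, plogis(scale(lia)[, 1])), geno$subject_ids)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    res <- prs_scan(geno, ss, y)
    res$best_threshold >= 1e-4 && res$best_threshold < 1e-2
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("compare_groups separates planted groups and rejects degenerate scores", {
  set.seed(84)
  n <- 80
  dos <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
  geno <- make_genotypes(dos)
  beta <- rnorm(20, 0, 0.3)
  ss <- make_sumstats(geno$snps$snp, geno$snps$bp, beta = beta,
                      p = rep(1e-4, 20))
  lia <- drop(dos %*% beta)
  y <- setNames(as.numeric(lia + rnorm(n, 0, 0.3) > median(lia)),
                geno$subject_ids)
  res <- prs_scan(geno, ss, y)
  cmp <- compare_groups(res)
  expect_lt(cmp$p, 0.01)
  expect_gt(cmp$statistic, 0)  # SCZ mean above HC mean

  res_const <- res
  res_const$scores[] <- 0
  expect_error(compare_groups(res_const),
               class = "areascan_degenerate_input")
})
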