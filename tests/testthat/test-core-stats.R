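test_that("welch_t matches the direct formula, t.test, and summary/sample equivalence", {
  x <- c(1, 2, 3)
  y <- c(4, 5, 6)
  res <- welch_t(x, y)
  oracle <- welch_oracle(x, y)
  expect_equal(res$statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(7 + i, 0, 1 + i / 5)
    b <- rnorm(12, 0.4, 2)
    res <- welch_t(a, b)
    tt <- t.test(a, b)
    expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    # summaries reproduce samples to 1e-12 relative
    sres <- welch_t(list(n = length(a), mean = mean(a), sd = sd(a)),
                    list(n = length(b), mean = mean(b), sd = sd(b)))
    expect_equal(sres$statistic, res$statistic, tolerance = 1e-12)
    expect_equal(sres$p, res$p, tolerance = 1e-12)
    # pooled form matches Student's t.test
    pres <- welch_t(a, b, pooled = TRUE)
    ptt <- t.test(a, b, var.equal = TRUE)
    expect_equal(pres$p, ptt$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t handles symmetric and degenerate inputs", {
  s <- list(n = 10, mean = 5, sd = 2)
  res <- welch_t(s, s)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  z <- list(n = 5, mean = 1, sd = 0)
  expect_equal(welch_t(z, z)$p, 1)
  expect_error(welch_t(c(1), c(2, 3)), class = "areascan_invalid_input")
  expect_error(welch_t(c(1, NA, 2), c(2, 3)), class = "areascan_invalid_input")
})

test_that("pearson_corr matches cor.test and is symmetric", {
  x <- 1:5
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)

  a <- c(1, 2, 3, 4)
  b <- c(2, 1, 4, 3)
  res <- pearson_corr(a, b)
  ct <- cor.test(a, b)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$test$p, ct$p.value, tolerance = 1e-12)
  swapped <- pearson_corr(b, a)
  expect_identical(swapped$r, res$r)
  expect_identical(swapped$test$p, res$test$p)

  expect_error(pearson_corr(rep(1, 4), b), class = "areascan_degenerate_input")
  expect_error(pearson_corr(1:3, 1:4), class = "areascan_invalid_input")
})

test_that("hwe_exact agrees with the enumeration oracle and respects symmetry", {
  expect_equal(hwe_exact(10, 0, 0), 1)
  expect_equal(hwe_exact(5, 10, 5), hwe_enum_oracle(5, 10, 5),
               tolerance = 1e-12)
  expect_equal(hwe_exact(2, 6, 12), hwe_exact(12, 6, 2), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:30) {
    cnt <- as.vector(rmultinom(1, sample(3:30, 1), runif(3)))
    expect_equal(hwe_exact(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10)
  }
  expect_error(hwe_exact(-1, 2, 3), class = "areascan_invalid_input")
})

test_that("single_case_test follows the Crawford-Howell form and its limits", {
  expect_equal(single_case_test(100, 100, 10, 50)$statistic, 0)
  expect_equal(single_case_test(100, 100, 10, 50)$p, 0.5)

  res <- single_case_test(80, 100, 10, 101)
  t_oracle <- -20 / (10 * sqrt(102 / 101))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 100)
  expect_equal(res$p, pt(t_oracle, 100), tolerance = 1e-12)

  # normal limit: large control sample, 1.96 sd below -> p ~ 0.025
  lim <- single_case_test(100 - 1.959964 * 10, 100, 10, 1e5)
  expect_equal(lim$p, 0.025, tolerance = 1e-3)

  # literal one-sample form uses sd/sqrt(n)
  os <- single_case_test(80, 100, 10, 101, form = "one_sample")
  expect_equal(os$statistic, -20 / (10 / sqrt(101)), tolerance = 1e-12)

  # p strictly decreasing in (mean_c - x)
  gaps <- seq(0, 3, by = 0.5)
  ps <- vapply(gaps, function(g) single_case_test(100 - g, 100, 5, 30)$p,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(single_case_test(1, 0, 0, 10), class = "areascan_degenerate_input")
  expect_error(single_case_test(1, 0, 1, 1), class = "areascan_invalid_input")
})

test_that("logistic_fit recovers the 2x2 cross-product ratio and matches glm", {
  # saturated 2x2: cases 30 exposed / 70 unexposed, controls 10 / 90
  y <- rep(c(1, 0), c(100, 100))
  g <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  fit <- logistic_fit(y, cbind(1, g))
  expect_true(fit$converged)
  expect_equal(unname(exp(fit$coefficients[2])), (30 * 90) / (70 * 10),
               tolerance = 1e-6)

  set.seed(21)
  x1 <- rnorm(80)
  x2 <- rbinom(80, 2, 0.4)
  yy <- rbinom(80, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  if (length(unique(yy)) == 1) yy[1] <- 1 - yy[1]
  X <- cbind(1, x1, x2)
  fit <- logistic_fit(yy, X)
  ref <- glm(yy ~ x1 + x2, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$standard_errors),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-5)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_true(all(fit$standard_errors > 0))

  # monotone log-likelihood trace and small score at convergence
  expect_true(all(diff(fit$ll_trace) > -1e-10))
  mu <- plogis(drop(X %*% fit$coefficients))
  expect_lt(max(abs(crossprod(X, yy - mu))), 1e-6)

  # recoding g -> 2 - g flips the slope sign exactly
  fit2 <- logistic_fit(yy, cbind(1, x1, 2 - x2))
  expect_equal(unname(fit2$coefficients[3]), unname(-fit$coefficients[3]), tolerance = 1e-8)
})

test_that("logistic_fit flags separation and rejects one-class outcomes", {
  y <- rep(c(0, 1), each = 20)
  g <- y  # perfect separation
  fit <- logistic_fit(y, cbind(1, g))
  expect_false(fit$converged)
  expect_error(logistic_fit(rep(1, 10), cbind(1, rnorm(10))),
               class = "areascan_invalid_input")
  expect_error(logistic_fit(y, cbind(1, rep(2, 40))),
               class = "areascan_invalid_input")

  # independence: balanced classes, random predictor -> slope near 0
  set.seed(5)
  slopes <- replicate(20, {
    yy <- rep(c(0, 1), each = 50)
    gg <- rnorm(100)
    logistic_fit(yy, cbind(1, gg))$coefficients[2]
  })
  expect_lt(abs(mean(slopes)), 0.1)
})

test_that("nagelkerke_r2 matches an independent likelihood-ratio evaluation", {
  set.seed(9)
  y <- c(0, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 0)
  s <- rnorm(12) + y
  fit <- glm(y ~ s, family = binomial())
  null <- glm(y ~ 1, family = binomial())
  n <- length(y)
  oracle <- (1 - exp((2 / n) * (logLik(null)[1] - logLik(fit)[1]))) /
    (1 - exp((2 / n) * logLik(null)[1]))
  ours <- nagelkerke_r2(logLik(null)[1], logLik(fit)[1], n)
  expect_equal(ours, oracle, tolerance = 1e-8)
  expect_gte(ours, 0)
  expect_lte(ours, 1)
})
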