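# Statistical primitives used by every downstream stage. These are the
# package's own implementations (formula-level), cross-checked in the test
# suite against independent routines (t.test, cor.test, glm, enumeration).

#' Construct a test result
#'
#' Container for a test statistic, its degrees of freedom and p-value.
#'
#' @param statistic numeric test statistic.
#' @param df degrees of freedom.
#' @param p p-value in \[0, 1\].
#' @param sided `"one"` or `"two"`.
#' @return an object of class `test_result`.
#' @export
test_result <- function(statistic, df, p, sided = c("two", "one")) {
  sided <- match.arg(sided)
  structure(list(statistic = statistic, df = df, p = p, sided = sided),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s-sided test: statistic = %.4f, df = %.2f, p = %.4g\n",
              x$sided, x$statistic, x$df, x$p))
  invisible(x)
}

# two-sided / one-sided (lower tail) p from a t statistic
t_pvalue <- function(t, df, sided) {
  if (sided == "two") 2 * pt(-abs(t), df) else pt(t, df)
}

#' Welch two-sample t-test from summaries or samples
#'
#' Computes the unequal-variance (Welch) two-sample t statistic
#' \eqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch-Satterthwaite degrees of freedom. Accepts either two numeric
#' sample vectors or two summary lists with elements `n`, `mean`, `sd`,
#' so published group summaries can be tested directly. A pooled-variance
#' (Student) form is available via `pooled = TRUE`.
#'
#' @param g1,g2 numeric vectors, or lists with `n`, `mean`, `sd`.
#' @param sided `"two"` (default) or `"one"`; the one-sided test is of
#'   the lower tail of the statistic as computed (g1 minus g2).
#' @param pooled use the pooled-variance Student form instead of Welch.
#' @return a [test_result].
#' @export
welch_t <- function(g1, g2, sided = c("two", "one"), pooled = FALSE) {
  sided <- match.arg(sided)
  summarize <- function(g) {
    if (is.list(g)) {
      if (!all(c("n", "mean", "sd") %in% names(g)))
        stop_invalid("summary input must have n, mean, sd")
      g <- list(n = g$n, mean = g$mean, sd = g$sd)
    } else {
      assert_finite(g, "sample values")
      g <- list(n = length(g), mean = mean(g), sd = sd(g))
    }
    assert_finite(unlist(g), "group summary")
    if (g$n < 2) stop_invalid("each group needs n >= 2")
    if (g$sd < 0) stop_invalid("sd must be non-negative")
    g
  }
  a <- summarize(g1); b <- summarize(g2)
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean) {
    return(test_result(0, a$n + b$n - 2, if (sided == "two") 1 else 0.5, sided))
  }
  if (pooled) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    v1 <- a$sd^2 / a$n
    v2 <- b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  }
  test_result(t, df, t_pvalue(t, df, sided), sided)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return a list with `r` and a two-sided [test_result] based on
#'   \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with \eqn{n-2} degrees of freedom.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 3) stop_invalid("need at least 3 paired observations")
  assert_finite(x, "x"); assert_finite(y, "y")
  if (sd(x) == 0 || sd(y) == 0) stop_degenerate("constant vector in correlation")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    res <- test_result(Inf * sign(r), n - 2, 0, "two")
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    res <- test_result(t, n - 2, t_pvalue(t, n - 2, "two"), "two")
  }
  list(r = r, test = res)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg proportions: conditioning on
#' the observed allele counts, sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed count (plain exact test, no mid-p correction).
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return the exact p-value.
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop_invalid("total genotype count must be >= 1")
  n_a <- 2 * n_hom_alt + n_het          # minor-allele-count convention free:
  if (n_a > n) {                        # condition on the rarer allele count
    n_a <- 2 * n - n_a
  }
  # attainable heterozygote counts share the parity of the allele count
  hets <- seq(n_a %% 2, n_a, by = 2)
  # log P(het = h | allele counts) up to a constant:
  #   n! / (hom_ref! het! hom_alt!) * 2^het, with hom_alt = (n_a - h)/2
  logp <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hrr <- n - h - haa
    h * log(2) - lfactorial(hrr) - lfactorial(h) - lfactorial(haa)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop_invalid("heterozygote count inconsistent with allele counts")
  # sum over configurations no more probable than observed (with a small
  # relative tolerance so ties are included despite rounding)
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Single-case versus control-sample test
#'
#' Tests whether one patient's value is drawn from the control
#' distribution. The default is the Crawford-Howell single-case form,
#' \eqn{t = (x - \bar{x}_c) / (s_c \sqrt{(n_c + 1)/n_c})} with
#' \eqn{n_c - 1} degrees of freedom, which treats the case as a single
#' new observation from the control population. The literal one-sample
#' form (divisor \eqn{s_c/\sqrt{n_c}}), which instead tests the control
#' mean against the patient value, is available via
#' `form = "one_sample"`.
#'
#' @param x the patient's value.
#' @param mean_c,sd_c,n_c control-sample mean, sd (> 0) and size (>= 2).
#' @param form `"crawford_howell"` (default) or `"one_sample"`.
#' @return a one-sided (lower-tail) [test_result]; small p means the
#'   patient's value is abnormally low relative to controls.
#' @export
single_case_test <- function(x, mean_c, sd_c, n_c,
                             form = c("crawford_howell", "one_sample")) {
  form <- match.arg(form)
  assert_finite(c(x, mean_c, sd_c, n_c), "single-case inputs")
  if (n_c < 2) stop_invalid("control sample needs n >= 2")
  if (sd_c <= 0) stop_degenerate("control sd must be positive")
  denom <- if (form == "crawford_howell") sd_c * sqrt((n_c + 1) / n_c)
           else sd_c / sqrt(n_c)
  t <- (x - mean_c) / denom
  test_result(t, n_c - 1, pt(t, n_c - 1), "one")
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with standard errors from the observed
#' information. Starts at zero coefficients; convergence is declared when
#' the log-likelihood change falls below `tol`. Complete or
#' quasi-separation is flagged heuristically (any fitted probability
#' within 1e-10 of 0 or 1, or any coefficient magnitude above 15) and
#' reported through `converged = FALSE`; callers must check the flag.
#'
#' @param y binary 0/1 outcome vector with both classes present.
#' @param X design matrix including the intercept column.
#' @param max_iter iteration cap (default 25).
#' @param tol convergence tolerance on the log-likelihood change.
#' @return an object of class `logistic_fit` with elements
#'   `coefficients`, `standard_errors`, `log_likelihood`, `converged`,
#'   `n_iterations`, `fitted` and `ll_trace`.
#' @export
logistic_fit <- function(y, X, max_iter = 25L, tol = 1e-8) {
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stop_invalid("y must be binary 0/1")
  if (length(unique(y)) < 2) stop_invalid("both outcome classes must be present")
  if (!all(is.finite(X))) stop_invalid("design matrix must be finite")
  if (nrow(X) != length(y)) stop_invalid("X and y dimensions disagree")
  if (qr(X)$rank < ncol(X)) stop_invalid("design matrix is rank deficient")

  p <- ncol(X)
  beta <- rep(0, p)
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  loglik <- function(mu) sum(y * log(mu) + (1 - y) * log(1 - mu))
  ll <- loglik(mu)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    xtw <- t(X * w)
    info <- xtw %*% X
    beta_new <- drop(solve(info, xtw %*% z))
    eta <- drop(X %*% beta_new)
    mu_new <- plogis(eta)
    mu_new <- pmin(pmax(mu_new, .Machine$double.xmin), 1 - 1e-16)
    ll_new <- loglik(mu_new)
    beta <- beta_new
    mu <- mu_new
    ll_trace <- c(ll_trace, ll_new)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  separated <- any(mu < 1e-10 | mu > 1 - 1e-10) || any(abs(beta) > 15)
  if (separated) converged <- FALSE
  se <- rep(NA_real_, p)
  ok <- tryCatch({
    se <- sqrt(diag(solve(info)))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) converged <- FALSE
  structure(list(coefficients = beta,
                 standard_errors = se,
                 log_likelihood = ll,
                 converged = converged,
                 n_iterations = iter,
                 fitted = mu,
                 ll_trace = ll_trace),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: ll = %.4f, %d iterations, converged = %s\n",
              x$log_likelihood, x$n_iterations, x$converged))
  print(data.frame(coef = x$coefficients, se = x$standard_errors))
  invisible(x)
}

# intercept-only logistic log-likelihood in closed form
null_loglik <- function(y) {
  n1 <- sum(y); n0 <- length(y) - n1
  p <- n1 / length(y)
  if (p == 0 || p == 1) return(0)
  n1 * log(p) + n0 * log(1 - p)
}

#' Nagelkerke pseudo-R-squared
#'
#' Normalized likelihood-ratio pseudo-R-squared for binary outcome
#' models: \eqn{(1 - \exp((2/n)(\ell_0 - \ell_1))) / (1 - \exp((2/n)\ell_0))},
#' where \eqn{\ell_0} is the intercept-only and \eqn{\ell_1} the full
#' model log-likelihood.
#'
#' @param ll0,ll1 null and full log-likelihoods.
#' @param n sample size.
#' @return the pseudo-R-squared, clipped to \[0, 1\].
#' @export
nagelkerke_r2 <- function(ll0, ll1, n) {
  r2 <- (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
  max(0, min(1, r2))
}
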