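# Independent oracles used across the suite. These deliberately use
# different algorithms / code paths from the package implementation.

# connected components by iterative minimum-label propagation over
# shifted arrays (vs the package's C++ breadth-first search); labels
# densified in column-major first-encounter order to match.
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offsets <- list()
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    m <- abs(a) + abs(b) + abs(c)
    if (m == 0) next
    if (connectivity == 6 && m > 1) next
    if (connectivity == 18 && m > 2) next
    offsets[[length(offsets) + 1]] <- c(a, b, c)
  }
  lab <- array(Inf, d)
  lab[mask] <- which(as.vector(mask))
  shift3 <- function(x, o) {
    out <- array(Inf, d)
    sx <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    sy <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    sz <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    out[sx, sy, sz] <- x[sx - o[1], sy - o[2], sz - o[3]]
    out
  }
  repeat {
    new_lab <- lab
    for (o in offsets) {
      sh <- shift3(lab, o)
      new_lab <- pmin(new_lab, sh)
    }
    new_lab[!mask] <- Inf
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  out <- array(0L, d)
  vals <- lab[mask]
  if (length(vals)) {
    # densify in column-major first-encounter order
    seen <- unique(as.vector(lab)[as.vector(lab) < Inf])
    out[mask] <- match(vals, seen)
  }
  out
}

# exact HWE p by full enumeration with factorial arithmetic (valid up
# to totals where (2n)! stays in double range; used for n <= 30)
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab   # count of the 'a' allele
  nb <- 2 * n - na
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  prob <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- (nb - h) / 2
    (factorial(n) / (factorial(aa) * factorial(h) * factorial(bb))) *
      2^h * factorial(na) * factorial(nb) / factorial(2 * n)
  }, numeric(1))
  obs <- prob[match(n_ab, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# Welch statistic by direct formula evaluation (independent of welch_t)
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force positional interval scan for SNP->gene mapping
interval_scan_oracle <- function(snps, annotation, window) {
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(annotation))) {
      if (snps$CHR[i] == annotation$chrom[j] &&
          snps$BP[i] >= annotation$start[j] - window &&
          snps$BP[i] <= annotation$end[j] + window) {
        rows[[length(rows) + 1]] <- data.frame(SNP = snps$SNP[i],
                                               gene = annotation$name[j])
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(SNP = character(0), gene = character(0))
}
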