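# Per-region phenotype derivation, genotype QC, logistic association
# scan, cross-region SNP sharing and positional SNP-to-gene mapping.

#' Derive a per-region case phenotype from regional volumes
#'
#' For each SCZ subject, tests their regional gray-matter volume
#' against the healthy-control sample with the single-case test
#' ([single_case_test()]); subjects with one-sided p below `alpha`
#' (volume abnormally low) become cases. Controls are all healthy
#' controls.
#'
#' @param volumes data frame (id, region, volume_cm3) as from
#'   [region_volume_table()].
#' @param cohort a cohort (provides group labels).
#' @param region region label to derive the phenotype for.
#' @param alpha one-sided selection threshold (default 0.05).
#' @param form single-case test form, see [single_case_test()].
#' @return an object of class `phenotype_assignment`: list with
#'   `region`, `case_ids`, `control_ids` and `patient_p` (named
#'   per-SCZ-subject p-values).
#' @export
derive_ba_phenotype <- function(volumes, cohort, region, alpha = 0.05,
                                form = "crawford_howell") {
  rows <- volumes[volumes$region == region, , drop = FALSE]
  if (nrow(rows) == 0) stop_invalid("no volumes for region %s", region)
  subj <- cohort$subjects
  v <- setNames(rows$volume_cm3, rows$id)
  hc_ids <- subj$id[subj$group == "HC"]
  scz_ids <- subj$id[subj$group == "SCZ"]
  hc_v <- v[hc_ids]
  if (sum(!is.na(hc_v)) < 2) stop_invalid("need >= 2 HC volumes for region %s", region)
  m <- mean(hc_v, na.rm = TRUE)
  s <- sd(hc_v, na.rm = TRUE)
  if (s <= 0) stop_degenerate("degenerate HC volume sample for region %s", region)
  n_c <- sum(!is.na(hc_v))
  patient_p <- vapply(scz_ids, function(id) {
    single_case_test(v[[id]], m, s, n_c, form = form)$p
  }, numeric(1))
  structure(list(region = region,
                 case_ids = scz_ids[patient_p < alpha],
                 control_ids = hc_ids,
                 patient_p = patient_p,
                 alpha = alpha),
            class = "phenotype_assignment")
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  cat(sprintf("region %s phenotype: %d cases (of %d SCZ), %d controls\n",
              x$region, length(x$case_ids), length(x$patient_p),
              length(x$control_ids)))
  invisible(x)
}

#' Genotype quality control
#'
#' Applies, in order: SNP call rate, subject call rate, minor-allele
#' frequency and control-group Hardy-Weinberg exact-test filters.
#' Defaults follow common GWAS practice (call rates 0.95, MAF 0.01,
#' HWE exact p 1e-6 in controls).
#'
#' @param genotypes a `genotype_matrix`.
#' @param cohort optional cohort; when given, HWE is tested in the HC
#'   group only, otherwise in all subjects.
#' @param snp_call_rate,subject_call_rate,maf_min,hwe_p thresholds.
#' @return list with the filtered `genotypes` and a `report` data frame
#'   (filter, removed) in application order.
#' @export
qc_genotypes <- function(genotypes, cohort = NULL,
                         snp_call_rate = 0.95, subject_call_rate = 0.95,
                         maf_min = 0.01, hwe_p = 1e-6) {
  dos <- genotypes$dosage
  snps <- genotypes$snps
  report <- data.frame(filter = character(0), removed = integer(0))
  note <- function(f, k) rbind(report, data.frame(filter = f, removed = k))

  snp_cr <- colMeans(!is.na(dos))
  drop_snp <- snp_cr < snp_call_rate
  report <- note("snp_call_rate", sum(drop_snp))
  dos <- dos[, !drop_snp, drop = FALSE]
  snps <- snps[!drop_snp, , drop = FALSE]

  subj_cr <- rowMeans(!is.na(dos))
  drop_subj <- subj_cr < subject_call_rate
  report <- rbind(report, data.frame(filter = "subject_call_rate",
                                     removed = sum(drop_subj)))
  dos <- dos[!drop_subj, , drop = FALSE]

  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  drop_maf <- is.na(maf) | maf < maf_min
  report <- rbind(report, data.frame(filter = "maf", removed = sum(drop_maf)))
  dos <- dos[, !drop_maf, drop = FALSE]
  snps <- snps[!drop_maf, , drop = FALSE]

  hwe_rows <- rownames(dos)
  if (!is.null(cohort)) {
    hc <- cohort$subjects$id[cohort$subjects$group == "HC"]
    hwe_rows <- intersect(rownames(dos), hc)
  }
  hwe_dos <- dos[hwe_rows, , drop = FALSE]
  hwe_pvals <- vapply(seq_len(ncol(hwe_dos)), function(j) {
    g <- hwe_dos[, j]
    hwe_exact(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
              sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  drop_hwe <- hwe_pvals < hwe_p
  report <- rbind(report, data.frame(filter = "hwe", removed = sum(drop_hwe)))
  dos <- dos[, !drop_hwe, drop = FALSE]
  snps <- snps[!drop_hwe, , drop = FALSE]

  if (ncol(dos) == 0) stop_invalid("all SNPs removed by quality control")
  out <- genotypes
  out$dosage <- dos
  out$snps <- snps
  out$subject_ids <- rownames(dos)
  list(genotypes = out, report = report)
}

# lean single-SNP logistic fit: y ~ intercept + g (no input validation;
# assoc_scan validates once). Returns beta, se, p, converged.
fit_snp_logistic <- function(y, g, max_iter = 25L, tol = 1e-8) {
  beta0 <- 0; beta1 <- 0
  eta <- rep(0, length(y))
  mu <- rep(0.5, length(y))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    sw <- sum(w); swg <- sum(w * g); swgg <- sum(w * g * g)
    det <- sw * swgg - swg^2
    if (!is.finite(det) || det <= 0) return(list(converged = FALSE))
    swz <- sum(w * z); swgz <- sum(w * g * z)
    beta0 <- (swgg * swz - swg * swgz) / det
    beta1 <- (sw * swgz - swg * swz) / det
    eta <- beta0 + beta1 * g
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, .Machine$double.xmin), 1 - 1e-16)
    ll_new <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(ll_new - ll) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  if (any(mu < 1e-10 | mu > 1 - 1e-10) || abs(beta1) > 15 || abs(beta0) > 15)
    converged <- FALSE
  w <- pmax(mu * (1 - mu), 1e-12)
  sw <- sum(w); swg <- sum(w * g); swgg <- sum(w * g * g)
  det <- sw * swgg - swg^2
  se <- sqrt(sw / det)
  z <- beta1 / se
  list(beta = beta1, se = se, p = 2 * pnorm(-abs(z)), converged = converged)
}

#' Per-SNP logistic association scan
#'
#' For each SNP, fits case status on additive dosage of the counted
#' allele by logistic regression (missing dosages mean-imputed per SNP)
#' and records the Wald test. SNPs below the significance threshold
#' (default the 5e-6 suggestive threshold) are flagged; non-converged
#' fits carry status `not_converged` and are never flagged.
#'
#' @param genotypes a `genotype_matrix`.
#' @param phenotype a `phenotype_assignment`.
#' @param threshold significance threshold on the Wald p.
#' @return an `assoc_table` data frame with columns CHR, BP, SNP, A1,
#'   A2, BETA, SE, OR, P, STATUS, SIGNIFICANT plus per-group genotype
#'   counts (N0_CASE..N2_CTRL).
#' @export
assoc_scan <- function(genotypes, phenotype, threshold = 5e-6) {
  case_ids <- intersect(phenotype$case_ids, rownames(genotypes$dosage))
  ctrl_ids <- intersect(phenotype$control_ids, rownames(genotypes$dosage))
  if (length(case_ids) < 1)
    stop_invalid("empty case set for region %s: re-derive the phenotype or lower alpha",
                 phenotype$region)
  if (length(ctrl_ids) < 1) stop_invalid("empty control set")
  ids <- c(case_ids, ctrl_ids)
  y <- c(rep(1, length(case_ids)), rep(0, length(ctrl_ids)))
  dos <- genotypes$dosage[ids, , drop = FALSE]
  m <- ncol(dos)
  snps <- genotypes$snps

  beta <- se <- p <- rep(NA_real_, m)
  status <- rep("ok", m)
  counts <- matrix(0L, m, 6,
                   dimnames = list(NULL, c("N0_CASE", "N1_CASE", "N2_CASE",
                                           "N0_CTRL", "N1_CTRL", "N2_CTRL")))
  for (j in seq_len(m)) {
    g <- dos[, j]
    for (k in 0:2) {
      counts[j, k + 1] <- sum(g == k & y == 1, na.rm = TRUE)
      counts[j, k + 4] <- sum(g == k & y == 0, na.rm = TRUE)
    }
    gm <- mean(g, na.rm = TRUE)
    if (!is.finite(gm) || var(g, na.rm = TRUE) == 0 || is.na(var(g, na.rm = TRUE))) {
      status[j] <- "excluded_qc"
      next
    }
    g[is.na(g)] <- gm
    fit <- fit_snp_logistic(y, g)
    if (!isTRUE(fit$converged)) {
      status[j] <- "not_converged"
      if (!is.null(fit$beta)) {
        beta[j] <- fit$beta; se[j] <- fit$se; p[j] <- fit$p
      }
      next
    }
    beta[j] <- fit$beta; se[j] <- fit$se; p[j] <- fit$p
  }
  out <- data.frame(CHR = snps$chr, BP = snps$bp, SNP = snps$snp,
                    A1 = snps$a1, A2 = snps$a2,
                    BETA = beta, SE = se, OR = exp(beta), P = p,
                    STATUS = status,
                    SIGNIFICANT = status == "ok" & !is.na(p) & p < threshold,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts))
  attr(out, "threshold") <- threshold
  attr(out, "n_case") <- length(case_ids)
  attr(out, "n_ctrl") <- length(ctrl_ids)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Cross-region table of shared significant SNPs
#'
#' @param per_region named list (region -> `assoc_table`).
#' @return data frame: one row per SNP significant anywhere, one
#'   logical column per region, plus `n_regions`; sorted by descending
#'   number of sharing regions (ties by SNP id).
#' @export
shared_snp_table <- function(per_region) {
  sig <- lapply(per_region, function(tab) tab$SNP[tab$SIGNIFICANT])
  all_snps <- sort(unique(unlist(sig)))
  if (length(all_snps) == 0) {
    out <- data.frame(SNP = character(0))
    for (r in names(per_region)) out[[r]] <- logical(0)
    out$n_regions <- integer(0)
    return(out)
  }
  out <- data.frame(SNP = all_snps, stringsAsFactors = FALSE)
  for (r in names(per_region)) out[[r]] <- all_snps %in% sig[[r]]
  out$n_regions <- rowSums(as.matrix(out[, names(per_region), drop = FALSE]))
  out[order(-out$n_regions, out$SNP), , drop = FALSE]
}

#' Positional SNP-to-gene mapping
#'
#' Maps each SNP to every gene whose interval, widened by the window,
#' contains its position. Coordinates are 1-based inclusive (VCF
#' convention); [read_gene_annotation_bed()] converts BED input on
#' read. Implemented over IRanges overlap machinery.
#'
#' @param snps an `assoc_table` (or data frame with SNP, CHR, BP).
#' @param annotation data frame with columns chrom, start, end, name
#'   (1-based inclusive).
#' @param window_kb symmetric window around gene bodies in kb (default
#'   10).
#' @param significant_only map only SNPs flagged significant (default
#'   TRUE when the column is present).
#' @return list with `mapped` (data frame SNP, CHR, BP, gene) and
#'   `unmapped` (character SNP ids).
#' @export
map_snps_to_genes <- function(snps, annotation, window_kb = 10,
                              significant_only = TRUE) {
  if (any(annotation$start > annotation$end))
    stop_invalid("malformed annotation interval (start > end)")
  tab <- as.data.frame(snps)
  if (significant_only && "SIGNIFICANT" %in% names(tab))
    tab <- tab[tab$SIGNIFICANT, , drop = FALSE]
  if (nrow(tab) == 0)
    return(list(mapped = data.frame(SNP = character(0), CHR = integer(0),
                                    BP = integer(0), gene = character(0)),
                unmapped = character(0)))
  w <- round(window_kb * 1000)
  mapped_rows <- list()
  unmapped <- character(0)
  for (chr in unique(tab$CHR)) {
    st <- tab[tab$CHR == chr, , drop = FALSE]
    an <- annotation[annotation$chrom == chr, , drop = FALSE]
    if (nrow(an) == 0) {
      unmapped <- c(unmapped, st$SNP)
      next
    }
    q <- IRanges::IRanges(start = st$BP, width = 1)
    s <- IRanges::IRanges(start = pmax(1, an$start - w), end = an$end + w)
    hits <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      mapped_rows[[length(mapped_rows) + 1]] <-
        data.frame(SNP = st$SNP[qh], CHR = chr, BP = st$BP[qh],
                   gene = an$name[sh], stringsAsFactors = FALSE)
    }
    unmapped <- c(unmapped, st$SNP[!seq_len(nrow(st)) %in% qh])
  }
  mapped <- if (length(mapped_rows)) do.call(rbind, mapped_rows)
            else data.frame(SNP = character(0), CHR = integer(0),
                            BP = integer(0), gene = character(0))
  list(mapped = mapped, unmapped = sort(unique(unmapped)))
}

#' Read a gene annotation BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based
#' inclusive on read.
#'
#' @param path BED path (>= 4 columns: chrom, start, end, name).
#' @return data frame with chrom, start, end, name (1-based inclusive).
#' @export
read_gene_annotation_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop_invalid("BED needs at least 4 columns")
  ann <- data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
                    name = bed[[4]], stringsAsFactors = FALSE)
  ann$chrom <- sub("^chr", "", ann$chrom)
  ann$chrom <- ifelse(grepl("^[0-9]+$", ann$chrom),
                      as.integer(ann$chrom), ann$chrom)
  ann
}
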