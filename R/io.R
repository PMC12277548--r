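# Genotype and summary-statistics input/output.

#' Write genotypes as a VCF with GT fields
#'
#' Emits a minimal VCFv4.2: REF = the non-counted allele (`a2`),
#' ALT = the counted allele (`a1`), unphased GT encoding the ALT
#' dosage, `./.` for missing.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  snps <- genotypes$snps
  dos <- genotypes$dosage
  gt_code <- c("0/0", "0/1", "1/1")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=areascan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(dos)),
                     collapse = "\t")), con)
  gt <- matrix("./.", nrow(dos), ncol(dos))
  for (k in 0:2) gt[!is.na(dos) & dos == k] <- gt_code[k + 1]
  lines <- vapply(seq_len(ncol(dos)), function(j) {
    paste(c(snps$chr[j], snps$bp[j], snps$snp[j], snps$a2[j], snps$a1[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from a VCF (GT fields)
#'
#' Parses with `vcfR`; the returned dosage counts the ALT allele.
#'
#' @param path VCF path.
#' @return a `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & x != "./." & x != ".|."
    parts <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(parts, function(p) sum(p == "1"), integer(1))
    out
  }
  dos <- t(apply(gt, 1, count_alt))
  colnames(dos) <- colnames(gt)
  fix <- vcfR::getFIX(v)
  snps <- data.frame(snp = unname(fix[, "ID"]),
                     chr = as.integer(fix[, "CHROM"]),
                     bp = as.integer(fix[, "POS"]),
                     a1 = unname(fix[, "ALT"]),
                     a2 = unname(fix[, "REF"]),
                     stringsAsFactors = FALSE)
  dos <- t(dos)
  snps$maf <- pmin(colMeans(dos, na.rm = TRUE) / 2,
                   1 - colMeans(dos, na.rm = TRUE) / 2)
  dimnames(dos) <- list(rownames(dos), snps$snp)
  structure(list(dosage = dos, snps = snps, subject_ids = rownames(dos)),
            class = "genotype_matrix")
}

#' Write / read genotypes as a dosage TSV
#'
#' Long header block (snp metadata columns) followed by one dosage
#' column per subject; missing as NA.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path TSV path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$snps[, c("snp", "chr", "bp", "a1", "a2")],
              as.data.frame(t(genotypes$dosage), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("snp", "chr", "bp", "a1", "a2")
  snps <- df[, meta_cols]
  dos <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(dos) <- snps$snp
  snps$maf <- pmin(colMeans(dos, na.rm = TRUE) / 2,
                   1 - colMeans(dos, na.rm = TRUE) / 2)
  structure(list(dosage = dos, snps = snps, subject_ids = rownames(dos)),
            class = "genotype_matrix")
}

#' Write / read summary statistics TSV
#'
#' Columns SNP, CHR, BP, A1, A2, BETA, SE, P.
#'
#' @param stats summary-stats data frame.
#' @param path TSV path.
#' @export
write_sumstats_tsv <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")
  if (!all(need %in% names(df)))
    stop_invalid("summary stats need columns %s", paste(need, collapse = ", "))
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Write an association table as a Manhattan-ready TSV
#'
#' @param tab an `assoc_table`.
#' @param path TSV path.
#' @export
write_assoc_tsv <- function(tab, path) {
  write_tsv_schema(as.data.frame(tab), path)
}
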