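# Developmental-expression statistics: positive-cell ratios, relative
# ISH intensities and areal pattern labels.

# The four measured cortical sites: two coronal planes (anterior /
# posterior) x two mediolateral positions. Order is fixed throughout.
ISH_REGIONS <- c("ant-medial", "ant-lateral", "pos-medial", "pos-lateral")

# canonical flag vectors (H/N/L per region, in ISH_REGIONS order) for
# each pattern label; used by the synthetic designer and as the
# reference vocabulary of the classifier
PATTERN_FLAGS <- list(
  "uniform"                              = c("N", "N", "N", "N"),
  "anteromedial-high"                    = c("H", "L", "L", "L"),
  "anterolateral-high"                   = c("L", "H", "L", "L"),
  "posteromedial-high"                   = c("L", "L", "H", "L"),
  "posterolateral-high"                  = c("L", "L", "L", "H"),
  "anteromedial-low"                     = c("L", "H", "H", "H"),
  "anterolateral-low"                    = c("H", "L", "H", "H"),
  "posteromedial-low"                    = c("H", "H", "L", "H"),
  "posterolateral-low"                   = c("H", "H", "H", "L"),
  "anterior-high posterior-low"          = c("H", "H", "L", "L"),
  "posterior-high anterior-low"          = c("L", "L", "H", "H"),
  "medial-high lateral-low"              = c("H", "L", "H", "L"),
  "lateral-high medial-low"              = c("L", "H", "L", "H"),
  "anterolateral and posteromedial-high" = c("L", "H", "H", "L"),
  "anteromedial and posterolateral-high" = c("H", "L", "L", "H")
)

#' Per-area positive-cell ratio
#'
#' For each requested gene and each area, the fraction of that area's
#' cells with a raw count at or above `min_count` (default 1, i.e. any
#' detected transcript counts as positive).
#'
#' @param matrix an expression matrix object: list with `counts`
#'   (gene x cell non-negative integer matrix, row names = genes) and
#'   `cell_meta` (data frame with columns `cell`, `area`, matching the
#'   count columns).
#' @param genes character vector of genes to tabulate.
#' @param min_count positivity threshold on the raw count.
#' @return a gene x area numeric matrix of ratios in \[0, 1\].
#' @export
positive_cell_ratio <- function(matrix, genes, min_count = 1L) {
  counts <- matrix$counts
  meta <- matrix$cell_meta
  missing <- setdiff(genes, rownames(counts))
  if (length(missing))
    stop_invalid("unknown gene(s): %s", paste(missing, collapse = ", "))
  if (ncol(counts) != nrow(meta))
    stop_invalid("cell metadata does not match count columns")
  areas <- sort(unique(meta$area))
  out <- sapply(areas, function(a) {
    cells <- which(meta$area == a)
    rowMeans(counts[genes, cells, drop = FALSE] >= min_count)
  })
  out <- base::matrix(out, nrow = length(genes),
                      dimnames = list(genes, areas))
  out
}

#' Relative ISH intensity across the four measured regions
#'
#' Normalizes the four regional intensities of one gene at one stage by
#' their mean, so the four relative values average to exactly 1.
#'
#' @param panel data frame with columns `gene`, `stage`, `region`,
#'   `intensity` (regions must be the four canonical sites).
#' @param gene,stage the (gene, stage) pair to extract.
#' @return named numeric vector of 4 relative intensities in the order
#'   ant-medial, ant-lateral, pos-medial, pos-lateral.
#' @export
relative_ish_intensity <- function(panel, gene, stage) {
  rows <- panel[panel$gene == gene & panel$stage == stage, , drop = FALSE]
  if (!setequal(rows$region, ISH_REGIONS) || nrow(rows) != 4)
    stop_invalid("need exactly the 4 regions for gene %s at stage %s",
                 gene, stage)
  vals <- setNames(rows$intensity[match(ISH_REGIONS, rows$region)],
                   ISH_REGIONS)
  if (any(vals < 0) || any(!is.finite(vals)))
    stop_invalid("intensities must be finite and non-negative")
  m <- mean(vals)
  if (m <= 0) stop_invalid("all-zero intensities for gene %s at %s", gene, stage)
  vals / m
}

#' Classify an areal expression pattern
#'
#' Maps four mean-normalized regional intensities to a pattern label.
#' Each region is flagged high (> 1 + delta), low (< 1 - delta) or
#' neutral, and the flags are mapped deterministically to the pattern
#' vocabulary, most specific rule first:
#' all neutral -> `uniform`; exactly two high regions -> the matching
#' paired label (`anterior-high posterior-low`, `posterior-high
#' anterior-low`, `medial-high lateral-low`, `lateral-high medial-low`,
#' `anterolateral and posteromedial-high`, `anteromedial and
#' posterolateral-high`); exactly one high region -> `<region>-high`;
#' exactly three high -> the remaining region's `<region>-low`; no high
#' but two low regions -> the complementary paired label; exactly one
#' low -> `<region>-low`; three low with no high cannot occur without a
#' high under mean normalization but would fall through to the single
#' remaining rule (`<region>-high` of the non-low region).
#'
#' @param relative numeric vector of 4 relative values averaging to 1
#'   (within 1e-6), ordered ant-medial, ant-lateral, pos-medial,
#'   pos-lateral.
#' @param delta high/low call margin (default 0.1).
#' @return the pattern label (character).
#' @export
classify_areal_pattern <- function(relative, delta = 0.1) {
  if (length(relative) != 4)
    stop_invalid("need 4 relative values")
  if (abs(mean(relative) - 1) > 1e-6)
    stop_invalid("relative values must average to 1")
  flags <- ifelse(relative > 1 + delta, "H",
                  ifelse(relative < 1 - delta, "L", "N"))
  names(flags) <- ISH_REGIONS
  hi <- ISH_REGIONS[flags == "H"]
  lo <- ISH_REGIONS[flags == "L"]
  region_word <- c("ant-medial" = "anteromedial",
                   "ant-lateral" = "anterolateral",
                   "pos-medial" = "posteromedial",
                   "pos-lateral" = "posterolateral")
  pair_label <- function(set) {
    if (setequal(set, c("ant-medial", "ant-lateral")))
      "anterior-high posterior-low"
    else if (setequal(set, c("pos-medial", "pos-lateral")))
      "posterior-high anterior-low"
    else if (setequal(set, c("ant-medial", "pos-medial")))
      "medial-high lateral-low"
    else if (setequal(set, c("ant-lateral", "pos-lateral")))
      "lateral-high medial-low"
    else if (setequal(set, c("ant-lateral", "pos-medial")))
      "anterolateral and posteromedial-high"
    else "anteromedial and posterolateral-high"
  }
  complement_pair <- function(set) pair_label(setdiff(ISH_REGIONS, set))
  if (length(hi) == 0 && length(lo) == 0) return("uniform")
  if (length(hi) == 2) return(pair_label(hi))
  if (length(hi) == 1) return(paste0(region_word[hi], "-high"))
  if (length(hi) == 3) return(paste0(region_word[setdiff(ISH_REGIONS, hi)], "-low"))
  if (length(hi) == 4) return("uniform")
  # no high region from here on
  if (length(lo) == 2) return(complement_pair(lo))
  if (length(lo) == 1) return(paste0(region_word[lo], "-low"))
  # three or four low without a high: label by the least-low region
  paste0(region_word[ISH_REGIONS[which.max(relative)]], "-high")
}

#' Classify every (gene, stage) in an ISH panel
#'
#' @param panel ISH data frame (gene, stage, region, intensity).
#' @param delta high/low margin passed to [classify_areal_pattern()].
#' @return data frame with columns gene, stage, pattern.
#' @export
classify_ish_panel <- function(panel, delta = 0.1) {
  keys <- unique(panel[, c("gene", "stage")])
  keys$pattern <- vapply(seq_len(nrow(keys)), function(i) {
    rel <- relative_ish_intensity(panel, keys$gene[i], keys$stage[i])
    classify_areal_pattern(rel, delta)
  }, character(1))
  rownames(keys) <- NULL
  keys
}

#' Read / write expression fixtures
#'
#' Counts are stored as TSV (genes x cells, first column `gene`) or
#' MatrixMarket (`.mtx` with `.rows`/`.cols` sidecars); cell metadata
#' and ISH panels as TSV.
#'
#' @param matrix expression matrix object (`counts` + `cell_meta`).
#' @param counts_path path ending in `.tsv` or `.mtx`.
#' @param meta_path cell-metadata TSV path.
#' @export
write_expression_matrix <- function(matrix, counts_path, meta_path) {
  if (grepl("\\.mtx$", counts_path)) {
    Matrix::writeMM(Matrix::Matrix(matrix$counts, sparse = TRUE), counts_path)
    writeLines(rownames(matrix$counts), paste0(counts_path, ".rows"))
    writeLines(colnames(matrix$counts), paste0(counts_path, ".cols"))
  } else {
    df <- data.frame(gene = rownames(matrix$counts), matrix$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_schema(matrix$cell_meta, meta_path)
  invisible(counts_path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(counts_path, meta_path) {
  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    rownames(m) <- readLines(paste0(counts_path, ".rows"))
    colnames(m) <- readLines(paste0(counts_path, ".cols"))
  } else {
    df <- read.delim(counts_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
  }
  storage.mode(m) <- "integer"
  list(counts = m, cell_meta = read_tsv_checked(meta_path))
}

#' @rdname write_expression_matrix
#' @param panel ISH data frame.
#' @param path TSV path.
#' @export
write_ish_tsv <- function(panel, path) write_tsv_schema(panel, path)

#' @rdname write_expression_matrix
#' @export
read_ish_tsv <- function(path) read_tsv_checked(path)
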