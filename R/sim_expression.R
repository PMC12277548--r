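# Expression fixture generators: area-labeled single-cell counts and
# staged ISH intensity panels with designed areal patterns.

#' Expression fixture design
#'
#' Describes the synthetic expression data: the cortical areas sampled
#' for the single-cell counts, cells per area, negative-binomial count
#' parameters, the area-preference multiplier for designed
#' area-preferential genes, and the ISH panel (stages, noise, high/low
#' multipliers). Each gene is assigned one designed ISH pattern per
#' stage by cycling through the pattern vocabulary, so every pattern is
#' represented.
#'
#' @param n_genes number of synthetic genes.
#' @param areas area names for the single-cell fixture.
#' @param cells_per_area cells sampled per area.
#' @param base_mean baseline negative-binomial mean per cell.
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param area_multiplier mean multiplier in a gene's preferred area.
#' @param stages ISH stages.
#' @param ish_high,ish_low intensity multipliers for designed high/low
#'   regions (neutral = 1).
#' @param ish_noise_cv lognormal coefficient of variation of ISH
#'   intensities around the designed means.
#' @return a list of class `expression_design`.
#' @export
expression_design <- function(n_genes = 16L,
                              areas = c("motor", "somatosensory",
                                        "prefrontal", "parietal",
                                        "temporal", "visual"),
                              cells_per_area = 40L,
                              base_mean = 0.8,
                              nb_size = 2,
                              area_multiplier = 4,
                              stages = c("E14.5", "E18.5", "P4"),
                              ish_high = 1.5,
                              ish_low = 0.6,
                              ish_noise_cv = 0.05) {
  structure(list(n_genes = as.integer(n_genes), areas = areas,
                 cells_per_area = as.integer(cells_per_area),
                 base_mean = base_mean, nb_size = nb_size,
                 area_multiplier = area_multiplier, stages = stages,
                 ish_high = ish_high, ish_low = ish_low,
                 ish_noise_cv = ish_noise_cv),
            class = "expression_design")
}

# designed regional multipliers for a pattern label
pattern_multipliers <- function(pattern, high = 1.5, low = 0.6) {
  flags <- PATTERN_FLAGS[[pattern]]
  if (is.null(flags)) stop_invalid("unknown pattern label: %s", pattern)
  setNames(ifelse(flags == "H", high, ifelse(flags == "L", low, 1)),
           ISH_REGIONS)
}

#' Generate expression fixtures
#'
#' Produces (i) a gene x cell negative-binomial count matrix with cells
#' labeled by cortical area, where every gene after the first has one
#' designed preferred area whose mean is multiplied by the configured
#' factor (the first gene is uniform across areas), and (ii) an ISH
#' intensity panel over the four canonical regions at each stage, drawn
#' around designed pattern means with lognormal noise. The designed
#' truth (preferred areas, pattern labels) is returned so recovery can
#' be scored.
#'
#' @param config a [sim_config()]; the `expression` element holds the
#'   [expression_design()].
#' @return list with `expression` (counts + cell_meta), `ish` (data
#'   frame gene, stage, region, intensity) and `design` (data frames
#'   `sc_truth` and `ish_truth`).
#' @export
generate_expression_fixtures <- function(config) {
  des <- config$expression
  set.seed(substream_seed(config$seed, "expression"))
  genes <- sprintf("sg%02d", seq_len(des$n_genes))
  n_areas <- length(des$areas)
  cells <- data.frame(
    cell = sprintf("c%04d", seq_len(n_areas * des$cells_per_area)),
    area = rep(des$areas, each = des$cells_per_area),
    stringsAsFactors = FALSE
  )
  pref <- c(NA_character_,
            des$areas[((seq_len(des$n_genes - 1) - 1) %% n_areas) + 1])
  counts <- matrix(0L, des$n_genes, nrow(cells),
                   dimnames = list(genes, cells$cell))
  for (g in seq_len(des$n_genes)) {
    mu <- rep(des$base_mean, nrow(cells))
    if (!is.na(pref[g])) {
      mu[cells$area == pref[g]] <- des$base_mean * des$area_multiplier
    }
    counts[g, ] <- as.integer(rnbinom(nrow(cells), mu = mu,
                                      size = des$nb_size))
  }

  vocab <- names(PATTERN_FLAGS)
  ish_rows <- list()
  truth_rows <- list()
  k <- 0
  sdlog <- sqrt(log(1 + des$ish_noise_cv^2))
  for (g in seq_len(des$n_genes)) {
    for (s in seq_along(des$stages)) {
      k <- k + 1
      pattern <- vocab[((g - 1) * length(des$stages) + s - 1) %% length(vocab) + 1]
      mult <- pattern_multipliers(pattern, des$ish_high, des$ish_low)
      intensity <- mult * rlnorm(4, -sdlog^2 / 2, sdlog)
      ish_rows[[k]] <- data.frame(gene = genes[g], stage = des$stages[s],
                                  region = ISH_REGIONS,
                                  intensity = unname(intensity),
                                  stringsAsFactors = FALSE)
      truth_rows[[k]] <- data.frame(gene = genes[g], stage = des$stages[s],
                                    pattern = pattern,
                                    stringsAsFactors = FALSE)
    }
  }
  list(expression = list(counts = counts, cell_meta = cells),
       ish = do.call(rbind, ish_rows),
       design = list(sc_truth = data.frame(gene = genes,
                                           preferred_area = pref,
                                           stringsAsFactors = FALSE),
                     ish_truth = do.call(rbind, truth_rows)))
}
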