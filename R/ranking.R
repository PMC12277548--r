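# Subsample permutation ranking of parcels by affected-voxel burden.

#' Affected-voxel proportions on one stratified subsample
#'
#' Draws a stratified subsample (the given fraction of each group,
#' rounded to nearest, without replacement), fits the voxel-wise GLM on
#' it, extracts suprathreshold clusters (voxel threshold plus extent
#' filter; no cluster-level FWE inside iterations), and returns, per
#' region, the number of surviving voxels divided by the region's voxel
#' count.
#'
#' @inheritParams fit_voxelwise_glm
#' @inheritParams extract_significant_clusters
#' @param fraction subsample fraction in (0, 1]; 1 reproduces the
#'   full-sample analysis deterministically.
#' @param seed seed for the subsample draw.
#' @param max_retry degenerate draws (fewer than 2 subjects in a group)
#'   are retried with the next substream, at most this many times.
#' @return named numeric vector of per-region proportions in \[0, 1\].
#' @export
subsample_affected_proportions <- function(images, cohort, atlas,
                                           fraction = 0.6,
                                           p_voxel = 0.001,
                                           min_size = 100L,
                                           seed = 1L,
                                           sided = "one",
                                           connectivity = 18L,
                                           max_retry = 10L) {
  if (fraction <= 0 || fraction > 1) stop_invalid("fraction must be in (0,1]")
  subj <- cohort$subjects
  for (attempt in 0:max_retry) {
    if (fraction == 1) {
      take <- seq_len(nrow(subj))
    } else {
      set.seed(substream_seed(seed, paste0("subsample_", attempt)))
      take <- unlist(lapply(split(seq_len(nrow(subj)), subj$group),
                            function(idx) {
                              k <- round(fraction * length(idx))
                              sort(sample(idx, k))
                            }), use.names = FALSE)
      take <- sort(take)
    }
    sub_subj <- subj[take, , drop = FALSE]
    if (min(table(sub_subj$group)) >= 2) {
      sub_cohort <- structure(list(subjects = sub_subj,
                                   case_flags = cohort$case_flags[take, , drop = FALSE],
                                   regions = cohort$regions),
                              class = "cohort")
      sub_images <- gm_image_set(images$data[, take, drop = FALSE],
                                 images$dim, images$voxel_size,
                                 images$subject_ids[take])
      tmap <- fit_voxelwise_glm(sub_images, sub_cohort, atlas)
      cl <- extract_significant_clusters(tmap, p_voxel, min_size,
                                         sided, connectivity)
      survived <- as.vector(cl$labels) > 0
      labs <- as.vector(atlas$grid)
      region_labels <- as.integer(names(atlas$labels))
      totals <- region_voxel_counts(atlas)
      affected <- vapply(region_labels,
                         function(l) sum(survived[labs == l]), numeric(1))
      return(setNames(affected / pmax(totals, 1), names(atlas$labels)))
    }
  }
  stop_invalid("could not draw a non-degenerate subsample")
}

#' Rank regions across iterations and select the top k
#'
#' Per iteration, regions are ranked by descending affected proportion
#' (rank 1 = most affected; ties broken by ascending region label).
#' The aggregate order sorts regions by ascending mean rank, breaking
#' ties by descending mean proportion; `top_k` is the first `k`.
#'
#' @param iteration_results list of per-region proportion vectors (all
#'   named identically).
#' @param k number of regions to select.
#' @return an object of class `ranking_result`: list with `proportions`
#'   (iterations x regions matrix), `ranks` (iterations x regions),
#'   `aggregate` (data frame region, mean_rank, mean_proportion,
#'   selected), `order` and `top_k`.
#' @export
rank_and_select <- function(iteration_results, k) {
  if (length(iteration_results) < 1) stop_invalid("need >= 1 iteration")
  props <- do.call(rbind, iteration_results)
  n_regions <- ncol(props)
  if (k > n_regions) stop_invalid("k exceeds number of regions")
  region_label <- as.integer(colnames(props))
  if (any(is.na(region_label))) region_label <- seq_len(n_regions)
  ranks <- t(apply(props, 1, function(p) {
    ord <- order(-p, region_label)
    r <- integer(n_regions)
    r[ord] <- seq_len(n_regions)
    r
  }))
  colnames(ranks) <- colnames(props)
  mean_rank <- colMeans(ranks)
  mean_prop <- colMeans(props)
  ord <- order(mean_rank, -mean_prop, region_label)
  agg <- data.frame(region = region_label[ord],
                    mean_rank = mean_rank[ord],
                    mean_proportion = mean_prop[ord],
                    selected = seq_len(n_regions) <= k,
                    stringsAsFactors = FALSE)
  structure(list(proportions = props, ranks = ranks, aggregate = agg,
                 order = region_label[ord],
                 top_k = region_label[ord][seq_len(k)]),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("ranking over %d iteration(s); top-%d: %s\n",
              nrow(x$proportions), length(x$top_k),
              paste(x$top_k, collapse = ", ")))
  invisible(x)
}

#' Run the full subsample ranking procedure
#'
#' Convenience wrapper: `n_iter` stratified subsamples of the given
#' fraction, each scored by [subsample_affected_proportions()], then
#' aggregated by [rank_and_select()]. Iteration seeds are derived as
#' substreams of `seed`.
#'
#' @inheritParams subsample_affected_proportions
#' @param n_iter number of subsample iterations (100 by default).
#' @param k number of regions to select (10 by default).
#' @return a `ranking_result`.
#' @export
run_ba_ranking <- function(images, cohort, atlas, n_iter = 100L,
                           fraction = 0.6, k = 10L, p_voxel = 0.001,
                           min_size = 100L, seed = 1L, sided = "one",
                           connectivity = 18L) {
  results <- lapply(seq_len(n_iter), function(i) {
    subsample_affected_proportions(images, cohort, atlas, fraction,
                                   p_voxel, min_size,
                                   seed = substream_seed(seed, paste0("iter_", i)),
                                   sided = sided,
                                   connectivity = connectivity)
  })
  rank_and_select(results, k)
}

#' Write a ranking result as two TSVs
#'
#' `<prefix>_proportions.tsv` holds the iterations x regions proportion
#' matrix; `<prefix>_aggregate.tsv` the aggregate table.
#'
#' @param result a `ranking_result`.
#' @param prefix output path prefix.
#' @export
write_ranking_tsv <- function(result, prefix) {
  props <- data.frame(iteration = seq_len(nrow(result$proportions)),
                      result$proportions, check.names = FALSE)
  write_tsv_schema(props, paste0(prefix, "_proportions.tsv"))
  write_tsv_schema(result$aggregate, paste0(prefix, "_aggregate.tsv"))
  invisible(prefix)
}
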