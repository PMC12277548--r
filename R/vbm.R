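# Voxel-wise group GLM, cluster extraction and permutation-based
# cluster-level family-wise error control.

#' Label connected components of a 3D mask
#'
#' Dense integer labels (1..k, in order of first column-major
#' encounter) of the connected components of a logical mask at 6-, 18-
#' or 26-connectivity.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param connectivity 6, 18 or 26 (18 is the default used throughout,
#'   the usual convention for cluster extraction in volumetric maps).
#' @return 3D integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  if (length(d) != 3) stop_invalid("mask must be a 3D array")
  .label_components_cpp(as.logical(mask), as.integer(d),
                        as.integer(connectivity))
}

#' Fit the voxel-wise group GLM
#'
#' Per voxel inside the atlas mask, ordinary least squares of
#' gray-matter density on \[intercept, group, sex, age, TIV\] (the
#' Gaussian-error GLM of volumetric morphometry, not a link-function
#' model). The map holds the t statistic of the group contrast,
#' oriented as HC minus SCZ, so positive t means gray-matter reduction
#' in the SCZ group; df = n - 5. Voxels with zero residual variance get
#' t = 0 and are flagged.
#'
#' @param images a [gm_image_set()].
#' @param cohort a cohort; `subjects` must contain `group`, `sex`,
#'   `age`, `tiv` and row order matching the image columns.
#' @param atlas a [label_volume] defining the analysis mask (nonzero
#'   labels).
#' @return an object of class `t_map`: list with `grid` (3D array, NaN
#'   outside the mask), `df`, `contrast`, and `zero_variance` (logical
#'   vector over masked voxels).
#' @export
fit_voxelwise_glm <- function(images, cohort, atlas) {
  check_grid_match(images, atlas)
  subj <- cohort$subjects
  if (!identical(subj$id, images$subject_ids))
    stop_invalid("cohort subjects and image set disagree")
  if (min(table(subj$group)) < 2)
    stop_invalid("need at least 2 subjects per group")
  X <- cbind(intercept = 1,
             scz = as.numeric(subj$group == "SCZ"),
             sex = subj$sex, age = subj$age, tiv = subj$tiv)
  fit_glm_tmap(images, X, atlas)
}

# shared engine: t-map for the second design column over masked voxels
fit_glm_tmap <- function(images, X, atlas) {
  n <- nrow(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop_invalid("design matrix is rank deficient")
  mask_idx <- which(as.vector(atlas$grid) > 0)
  Y <- images$data[mask_idx, , drop = FALSE]   # voxels x subjects
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- xtx_inv %*% crossprod(X, t(Y))          # p x voxels
  resid <- t(Y) - X %*% B                      # subjects x voxels
  rss <- colSums(resid^2)
  df <- n - p
  sigma2 <- rss / df
  zero_var <- sigma2 < 1e-24
  se <- sqrt(xtx_inv[2, 2] * sigma2)
  tval <- ifelse(zero_var, 0, -B[2, ] / se)    # HC - SCZ orientation
  grid <- array(NaN, dim(atlas$grid))
  grid[mask_idx] <- tval
  structure(list(grid = grid, df = df, contrast = "HC-SCZ",
                 zero_variance = zero_var, mask_idx = mask_idx),
            class = "t_map")
}

#' @export
print.t_map <- function(x, ...) {
  v <- x$grid[is.finite(x$grid)]
  cat(sprintf("t-map (%s, df = %d): %d voxels, t range [%.2f, %.2f]\n",
              x$contrast, x$df, length(v), min(v), max(v)))
  invisible(x)
}

#' Extract suprathreshold clusters from a t-map
#'
#' Thresholds the t-map at the voxel-level p-value (one-sided in the
#' HC > SCZ direction by default, i.e. gray-matter decrease in SCZ;
#' two-sided uses |t|), labels connected components, and discards
#' components smaller than `min_size` voxels. Defaults: voxel p 0.001,
#' minimum extent 100 voxels.
#'
#' @param tmap a `t_map`.
#' @param p_voxel voxel-level uncorrected p threshold, in (0, 1).
#' @param min_size minimum cluster extent in voxels (>= 1).
#' @param sided `"one"` (default) or `"two"`.
#' @param connectivity 6, 18 or 26.
#' @return an object of class `cluster_set`: list with `labels` (3D
#'   integer array, clusters renumbered densely from 1 in decreasing
#'   size order) and `clusters` (data frame id, n_voxels, peak_t, x, y,
#'   z, p_fwe = NA).
#' @export
extract_significant_clusters <- function(tmap, p_voxel = 0.001,
                                         min_size = 100L,
                                         sided = c("one", "two"),
                                         connectivity = 18L) {
  sided <- match.arg(sided)
  if (p_voxel <= 0 || p_voxel >= 1) stop_invalid("p_voxel must be in (0,1)")
  if (min_size < 1) stop_invalid("min_size must be >= 1")
  thr <- if (sided == "one") qt(1 - p_voxel, tmap$df)
         else qt(1 - p_voxel / 2, tmap$df)
  supra <- if (sided == "one") tmap$grid > thr else abs(tmap$grid) > thr
  supra[!is.finite(tmap$grid)] <- FALSE
  comp <- label_components(supra, connectivity)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= min_size)
  labels <- array(0L, dim(comp))
  clusters <- data.frame(id = integer(0), n_voxels = integer(0),
                         peak_t = numeric(0), x = integer(0),
                         y = integer(0), z = integer(0),
                         p_fwe = numeric(0))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], keep)]
    rows <- vector("list", length(keep))
    for (i in seq_along(keep)) {
      vox <- which(comp == keep[i])
      labels[vox] <- i
      tvals <- if (sided == "one") tmap$grid[vox] else abs(tmap$grid[vox])
      peak <- vox[which.max(tvals)]
      pc <- arrayInd(peak, dim(comp))
      rows[[i]] <- data.frame(id = i, n_voxels = length(vox),
                              peak_t = tmap$grid[peak],
                              x = pc[1], y = pc[2], z = pc[3],
                              p_fwe = NA_real_)
    }
    clusters <- do.call(rbind, rows)
  }
  structure(list(labels = labels, clusters = clusters,
                 p_voxel = p_voxel, min_size = min_size,
                 sided = sided, connectivity = connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d cluster(s) at voxel p < %g, extent >= %d\n",
              nrow(x$clusters), x$p_voxel, x$min_size))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Permutation-based cluster-level family-wise error correction
#'
#' Builds the null distribution of the maximum suprathreshold component
#' extent by permuting group labels across subjects (covariates stay
#' attached to their subjects), refitting the voxel-wise GLM each time.
#' Each observed cluster gets
#' p = (1 + #\{permutation max extent >= observed extent\}) / (n_perm + 1);
#' clusters with p < 0.05 are flagged significant. The permutation null
#' uses all suprathreshold components (no extent filter), which makes
#' the correction conservative for the min-size-filtered observed
#' clusters.
#'
#' @inheritParams fit_voxelwise_glm
#' @inheritParams extract_significant_clusters
#' @param n_perm number of permutations (>= 100; a warning is issued if
#'   fewer than 199, too few to resolve p = 0.05 sharply).
#' @param seed integer seed for the permutation stream.
#' @param alpha cluster-level significance threshold (default 0.05).
#' @return a `cluster_set` whose `clusters` carry `p_fwe` and
#'   `significant`.
#' @export
cluster_fwe_permutation <- function(images, cohort, atlas,
                                    p_voxel = 0.001, min_size = 100L,
                                    n_perm = 200L, seed = 1L,
                                    sided = c("one", "two"),
                                    connectivity = 18L, alpha = 0.05) {
  sided <- match.arg(sided)
  if (n_perm < 100) stop_invalid("n_perm must be >= 100")
  if (n_perm < 199) warning("n_perm < 199 resolves cluster p coarsely near 0.05")
  tmap <- fit_voxelwise_glm(images, cohort, atlas)
  obs <- extract_significant_clusters(tmap, p_voxel, min_size, sided,
                                      connectivity)
  if (nrow(obs$clusters) == 0) return(obs)

  subj <- cohort$subjects
  base_X <- cbind(intercept = 1, scz = as.numeric(subj$group == "SCZ"),
                  sex = subj$sex, age = subj$age, tiv = subj$tiv)
  thr <- if (sided == "one") qt(1 - p_voxel, tmap$df)
         else qt(1 - p_voxel / 2, tmap$df)
  set.seed(seed)
  max_extent <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Xp <- base_X
    Xp[, "scz"] <- base_X[sample.int(nrow(base_X)), "scz"]
    tm <- fit_glm_tmap(images, Xp, atlas)
    supra <- if (sided == "one") tm$grid > thr else abs(tm$grid) > thr
    supra[!is.finite(tm$grid)] <- FALSE
    comp <- label_components(supra, connectivity)
    max_extent[b] <- if (any(comp > 0)) max(tabulate(comp[comp > 0])) else 0
  }
  obs$clusters$p_fwe <- vapply(obs$clusters$n_voxels, function(k) {
    (1 + sum(max_extent >= k)) / (n_perm + 1)
  }, numeric(1))
  obs$clusters$significant <- obs$clusters$p_fwe < alpha
  obs$null_max_extent <- max_extent
  obs
}

#' Write a t-map or cluster labels as NIfTI, and a cluster table as TSV
#'
#' @param tmap a `t_map`.
#' @param path output path.
#' @export
write_tmap_nifti <- function(tmap, path) {
  RNifti::writeNifti(RNifti::asNifti(tmap$grid), path)
  invisible(path)
}

#' @rdname write_tmap_nifti
#' @param clusters a `cluster_set`.
#' @export
write_cluster_table <- function(clusters, path) {
  write_tsv_schema(clusters$clusters, path)
}
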