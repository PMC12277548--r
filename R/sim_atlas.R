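# Phantom parcellation generator.

#' Generate a phantom parcellated atlas
#'
#' Builds a Brodmann-map stand-in: an ellipsoidal brain mask inside the
#' configured grid, partitioned into `n_regions` contiguous parcels by
#' Voronoi growth from random seed points followed by a few Lloyd
#' relaxations (which even out parcel sizes). Label 0 is background.
#' Each Voronoi cell is the intersection of a convex polytope with the
#' ellipsoid, so parcels are connected; a configuration error is raised
#' if after several reseeding attempts some parcel stays below
#' `min_region_voxels`.
#'
#' @param config a [sim_config()].
#' @param min_region_voxels minimum parcel size (voxels).
#' @return a [label_volume] with regions labeled 1..n_regions.
#' @export
generate_phantom_atlas <- function(config, min_region_voxels = 150L) {
  set.seed(substream_seed(config$seed, "atlas"))
  shape <- config$grid_shape
  n_regions <- config$n_regions
  # ellipsoidal mask with semi-axes at 45% of each grid extent
  centers <- (shape + 1) / 2
  semi <- shape * 0.45
  ax <- (seq_len(shape[1]) - centers[1]) / semi[1]
  ay <- (seq_len(shape[2]) - centers[2]) / semi[2]
  az <- (seq_len(shape[3]) - centers[3]) / semi[3]
  d2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  mask <- d2 <= 1
  n_mask <- sum(mask)
  if (n_mask < n_regions * min_region_voxels)
    stop_config("grid too small: %d mask voxels for %d regions of >= %d voxels",
                n_mask, n_regions, min_region_voxels)
  coords <- which(mask, arr.ind = TRUE)
  for (attempt in 1:20) {
    seeds <- coords[sample.int(nrow(coords), n_regions), , drop = FALSE]
    assign <- nearest_seed(coords, seeds)
    for (lloyd in 1:6) {
      seeds <- t(vapply(seq_len(n_regions), function(r) {
        colMeans(coords[assign == r, , drop = FALSE])
      }, numeric(3)))
      assign <- nearest_seed(coords, seeds)
    }
    if (min(tabulate(assign, n_regions)) >= min_region_voxels) {
      grid <- array(0L, shape)
      grid[mask] <- assign
      return(label_volume(grid, config$voxel_size_mm,
                          setNames(paste0("BA", seq_len(n_regions)),
                                   as.character(seq_len(n_regions)))))
    }
  }
  stop_config("could not place %d regions of >= %d voxels in the mask",
              n_regions, min_region_voxels)
}

nearest_seed <- function(coords, seeds) {
  d <- matrix(0, nrow(coords), nrow(seeds))
  for (k in 1:3) d <- d + outer(coords[, k], seeds[, k], `-`)^2
  max.col(-d, ties.method = "first")
}
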