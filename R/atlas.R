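# Label-volume handling: construction, merging, voxel counts and
# density-weighted regional volumes.

#' Construct a label volume
#'
#' A parcellation: a 3D non-negative integer grid with voxel sizes and a
#' label -> region-name map. Label 0 is reserved for background.
#'
#' @param grid 3D integer array; 0 = background.
#' @param voxel_size mm per axis (length 3).
#' @param labels named character vector mapping label values (names) to
#'   region names; must cover every nonzero value in `grid`.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(grid, voxel_size = c(1, 1, 1), labels = NULL) {
  if (length(dim(grid)) != 3) stop_invalid("grid must be a 3D array")
  if (any(grid < 0) || any(grid != round(grid)))
    stop_invalid("grid values must be non-negative integers")
  vals <- sort(unique(as.integer(grid[grid > 0])))
  if (is.null(labels)) {
    labels <- setNames(paste0("region_", vals), as.character(vals))
  }
  missing <- setdiff(as.character(vals), names(labels))
  if (length(missing))
    stop_invalid("labels missing for grid values: %s",
                 paste(missing, collapse = ", "))
  structure(list(grid = array(as.integer(grid), dim(grid)),
                 voxel_size = as.numeric(voxel_size),
                 labels = labels,
                 provenance = setNames(rep("base", length(labels)),
                                       names(labels))),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label volume: %s grid, %d regions, voxel %s mm\n",
              paste(dim(x$grid), collapse = "x"),
              length(x$labels),
              paste(x$voxel_size, collapse = "x")))
  invisible(x)
}

#' Merge supplementary label volumes into a base parcellation
#'
#' Combines a base atlas with supplementary label volumes (e.g. parcels
#' missing from the base map and recovered from other atlases). In
#' `fill` mode (default) supplement labels claim only voxels the base
#' leaves as background; in `override` mode they replace base labels.
#' Label namespaces must be disjoint unless `remap` renames colliding
#' supplement labels; a supplement entry identical to an existing one
#' (same label value and region name) is tolerated, which makes the
#' merge idempotent. Merge provenance is recorded per label.
#'
#' @param base a [label_volume].
#' @param supplements list of [label_volume]s on the same grid.
#' @param mode `"fill"` or `"override"`.
#' @param remap optional named integer vector renaming supplement labels
#'   (names = old values).
#' @return the merged [label_volume].
#' @export
merge_label_volumes <- function(base, supplements, mode = c("fill", "override"),
                                remap = NULL) {
  mode <- match.arg(mode)
  if (inherits(supplements, "label_volume")) supplements <- list(supplements)
  grid <- base$grid
  labels <- base$labels
  prov <- base$provenance
  for (i in seq_along(supplements)) {
    sup <- supplements[[i]]
    if (!identical(dim(sup$grid), dim(grid)))
      stop_invalid("supplement %d grid shape differs from base", i)
    if (!isTRUE(all.equal(sup$voxel_size, base$voxel_size)))
      stop_invalid("supplement %d voxel size differs from base", i)
    sgrid <- sup$grid
    slabels <- sup$labels
    if (!is.null(remap)) {
      old <- as.integer(names(remap))
      for (k in seq_along(old)) {
        sgrid[sup$grid == old[k]] <- remap[k]
      }
      names(slabels) <- as.character(remap[match(names(slabels),
                                                 names(remap))])
    }
    # a collision is only an error when the same label value names a
    # different region; identical entries make the merge idempotent
    collide <- intersect(names(slabels), names(labels))
    conflict <- collide[labels[collide] != slabels[collide]]
    if (length(conflict))
      stop_invalid("label collision without remap: %s",
                   paste(conflict, collapse = ", "))
    slabels <- slabels[setdiff(names(slabels), collide)]
    take <- if (mode == "fill") sgrid > 0 & grid == 0 else sgrid > 0
    grid[take] <- sgrid[take]
    labels <- c(labels, slabels)
    prov <- c(prov, setNames(rep(sprintf("supplement_%d:%s", i, mode),
                                 length(slabels)), names(slabels)))
  }
  # drop label entries whose voxels were completely overwritten
  present <- as.character(sort(unique(as.integer(grid[grid > 0]))))
  out <- label_volume(grid, base$voxel_size, labels[present])
  out$provenance <- prov[present]
  out
}

#' Voxel counts per region
#'
#' @param atlas a [label_volume].
#' @param mask optional logical/0-1 array of the same shape restricting
#'   the tally.
#' @return named integer vector, label -> voxel count, for every label
#'   in the atlas (zero where masked out).
#' @export
region_voxel_counts <- function(atlas, mask = NULL) {
  grid <- atlas$grid
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(grid)))
      stop_invalid("mask shape differs from atlas grid")
    grid <- grid * (mask != 0)
  }
  counts <- setNames(rep(0L, length(atlas$labels)), names(atlas$labels))
  tab <- table(grid[grid > 0])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Density-weighted regional gray-matter volume
#'
#' Computes, per subject, the modulated-VBM convention volume of a
#' region: the sum of gray-matter density over the region's voxels times
#' the voxel volume (mm^3), converted to cm^3. A binary mode
#' (`binary = TRUE`) counts voxels with density above 0.5 instead.
#'
#' @param images a `gm_image_set` (see [generate_gm_images()]).
#' @param atlas a [label_volume] on the same grid.
#' @param label region label (integer) present in the atlas; the special
#'   value `0` is not allowed. Use [whole_brain_volume()] for the
#'   whole-mask volume.
#' @param binary count voxels above 0.5 density instead of summing
#'   density.
#' @return named numeric vector of per-subject volumes in cm^3.
#' @export
regional_gm_volume <- function(images, atlas, label, binary = FALSE) {
  check_grid_match(images, atlas)
  if (!as.character(label) %in% names(atlas$labels))
    stop_invalid("unknown region label %s", label)
  idx <- which(as.vector(atlas$grid) == label)
  voxvol <- prod(atlas$voxel_size)
  dens <- images$data[idx, , drop = FALSE]
  if (binary) dens <- (dens > 0.5) + 0
  setNames(colSums(dens) * voxvol / 1000, images$subject_ids)
}

#' Whole-brain gray-matter volume per subject
#'
#' @inheritParams regional_gm_volume
#' @return named numeric vector in cm^3 (sum over all nonzero-label
#'   voxels).
#' @export
whole_brain_volume <- function(images, atlas, binary = FALSE) {
  check_grid_match(images, atlas)
  idx <- which(as.vector(atlas$grid) > 0)
  voxvol <- prod(atlas$voxel_size)
  dens <- images$data[idx, , drop = FALSE]
  if (binary) dens <- (dens > 0.5) + 0
  setNames(colSums(dens) * voxvol / 1000, images$subject_ids)
}

#' Per-subject, per-region volume table
#'
#' @inheritParams regional_gm_volume
#' @return data frame with columns `id`, `region`, `volume_cm3`.
#' @export
region_volume_table <- function(images, atlas, binary = FALSE) {
  labs <- as.integer(names(atlas$labels))
  rows <- lapply(labs, function(l) {
    v <- regional_gm_volume(images, atlas, l, binary = binary)
    data.frame(id = names(v), region = l, volume_cm3 = unname(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

check_grid_match <- function(images, atlas) {
  if (!identical(images$dim, dim(atlas$grid)))
    stop_invalid("image grid %s does not match atlas grid %s",
                 paste(images$dim, collapse = "x"),
                 paste(dim(atlas$grid), collapse = "x"))
}

#' NIfTI input/output for label and density volumes
#'
#' Label volumes are written as NIfTI with an identity affine scaled by
#' the voxel size, plus a sidecar TSV (`<path>.labels.tsv`) carrying the
#' label -> name map.
#'
#' @param atlas a [label_volume].
#' @param path output `.nii.gz` path.
#' @export
write_label_volume_nifti <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$grid)
  RNifti::pixdim(img) <- atlas$voxel_size
  RNifti::writeNifti(img, path)
  write.table(data.frame(label = as.integer(names(atlas$labels)),
                         name = unname(atlas$labels)),
              paste0(path, ".labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_volume_nifti
#' @export
read_label_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  voxdim <- RNifti::pixdim(img)[1:3]
  labels <- NULL
  side <- paste0(path, ".labels.tsv")
  if (file.exists(side)) {
    tab <- read.delim(side, stringsAsFactors = FALSE)
    labels <- setNames(tab$name, as.character(tab$label))
  }
  label_volume(array(as.integer(round(img)), dim(img)[1:3]), voxdim, labels)
}
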