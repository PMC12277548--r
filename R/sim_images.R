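# Gray-matter image generator and image-set container.

#' Construct a gray-matter image set
#'
#' @param data voxels x subjects numeric matrix (column-major voxel
#'   order of the grid).
#' @param dim grid dimensions (length 3).
#' @param voxel_size mm per axis.
#' @param subject_ids character subject ids (one per column).
#' @return an object of class `gm_image_set`.
#' @export
gm_image_set <- function(data, dim, voxel_size, subject_ids) {
  dim <- as.integer(dim)
  if (nrow(data) != prod(dim)) stop_invalid("data rows do not match grid size")
  if (ncol(data) != length(subject_ids))
    stop_invalid("one subject id per image required")
  structure(list(data = data, dim = dim, voxel_size = as.numeric(voxel_size),
                 subject_ids = subject_ids),
            class = "gm_image_set")
}

#' @export
print.gm_image_set <- function(x, ...) {
  cat(sprintf("gm image set: %d subjects on a %s grid\n",
              ncol(x$data), paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Generate per-subject gray-matter density images
#'
#' Voxel model inside the brain mask: a smooth regional baseline plus
#' linear covariate effects (sex, age, TIV), a deficit of
#' `-gm_effect_d * noise_sd` in affected regions for subjects whose
#' per-region case flag is set, and i.i.d. Gaussian voxel noise of sd
#' `noise_sd`. Background voxels are zero. Affected regions are the
#' cohort's flagged regions (by default the configuration's
#' `affected_regions`).
#'
#' @param config a [sim_config()].
#' @param cohort a cohort (case flags decide who carries the deficit
#'   where).
#' @param atlas a [label_volume] on the configured grid.
#' @return a [gm_image_set()].
#' @export
generate_gm_images <- function(config, cohort, atlas) {
  if (!identical(dim(atlas$grid), config$grid_shape))
    stop_invalid("atlas grid does not match configured grid shape")
  set.seed(substream_seed(config$seed, "images"))
  n <- nrow(cohort$subjects)
  labs <- as.vector(atlas$grid)
  inside <- labs > 0
  n_vox <- length(labs)

  # per-region baselines around a typical gray-matter density
  baselines <- rnorm(config$n_regions, 0.60, 0.03)
  base_map <- numeric(n_vox)
  base_map[inside] <- baselines[labs[inside]]

  ce <- config$covariate_effects
  subj <- cohort$subjects
  shift <- ce[["sex"]] * subj$sex +
    ce[["age"]] * (subj$age - mean(subj$age)) +
    ce[["tiv"]] * (subj$tiv - mean(subj$tiv))

  deficit <- config$gm_effect_d * config$noise_sd
  data <- matrix(0, n_vox, n)
  for (s in seq_len(n)) {
    img <- base_map + shift[s] * inside
    affected <- which(cohort$case_flags[s, ])
    if (length(affected)) {
      img[labs %in% cohort$regions[affected]] <-
        img[labs %in% cohort$regions[affected]] - deficit
    }
    if (config$noise_sd > 0) {
      img[inside] <- img[inside] + rnorm(sum(inside), 0, config$noise_sd)
    }
    data[, s] <- img
  }
  gm_image_set(data, config$grid_shape, config$voxel_size_mm, subj$id)
}

#' Write / read a gray-matter image set as NIfTI files
#'
#' One `.nii.gz` per subject, named by subject id, with identity affine
#' scaled by the voxel size.
#'
#' @param images a [gm_image_set()].
#' @param dir output directory (created if needed).
#' @export
write_gm_images_nifti <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(images$subject_ids)) {
    img <- RNifti::asNifti(array(images$data[, s], images$dim))
    RNifti::pixdim(img) <- images$voxel_size
    RNifti::writeNifti(img,
                       file.path(dir, paste0(images$subject_ids[s], ".nii.gz")))
  }
  invisible(dir)
}

#' @rdname write_gm_images_nifti
#' @param ids subject ids to read (default: all `.nii.gz` in `dir`).
#' @export
read_gm_images_nifti <- function(dir, ids = NULL) {
  if (is.null(ids)) {
    files <- sort(list.files(dir, pattern = "\\.nii\\.gz$"))
    ids <- sub("\\.nii\\.gz$", "", files)
  }
  imgs <- lapply(ids, function(id) {
    RNifti::readNifti(file.path(dir, paste0(id, ".nii.gz")))
  })
  d <- dim(imgs[[1]])[1:3]
  voxdim <- RNifti::pixdim(imgs[[1]])[1:3]
  data <- vapply(imgs, function(x) as.vector(x), numeric(prod(d)))
  gm_image_set(data, d, voxdim, ids)
}
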