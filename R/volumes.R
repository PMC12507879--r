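#' Intensity volumes and ROI masks
#'
#' An `intensity_volume` is a 3-D voxel grid with millimetre spacing and a
#' modality tag (`"CT"` or `"MRI"`); a `roi_mask` is a binary grid of the same
#' shape marking the paraspinal-muscle region of interest. These are the two
#' imaging inputs of the habitat pipeline.
#'
#' @param voxels A 3-D numeric array (for masks: logical or 0/1).
#' @param spacing Voxel spacing in mm, a positive length-3 numeric.
#' @param modality `"CT"` or `"MRI"`.
#'
#' @return An object of class `intensity_volume` (resp. `roi_mask`).
#' @export
#' @examples
#' v <- intensity_volume(array(rnorm(60), c(5, 4, 3)), c(1, 1, 1), "CT")
#' m <- roi_mask(array(TRUE, c(5, 4, 3)), c(1, 1, 1))
intensity_volume <- function(voxels, spacing = c(1, 1, 1), modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  voxels <- as_grid3(voxels, "voxels")
  check_spacing(spacing)
  if (!all(is.finite(voxels))) {
    abort("all voxel intensities must be finite", class = "sarcohab_input_error")
  }
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing), modality = modality),
    class = "intensity_volume"
  )
}

#' @rdname intensity_volume
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as_grid3(voxels, "mask voxels")
  check_spacing(spacing)
  if (!all(voxels %in% c(0, 1))) {
    abort("mask voxels must be binary (0/1)", class = "sarcohab_input_error")
  }
  voxels <- array(voxels != 0, dim = dim(voxels))
  if (!any(voxels)) {
    abort("mask has no foreground voxels", class = "sarcohab_empty_roi_error")
  }
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing)),
    class = "roi_mask"
  )
}

as_grid3 <- function(x, what) {
  if (is.null(dim(x)) || length(dim(x)) != 3 || any(dim(x) < 1)) {
    abort(paste(what, "must be a non-empty 3-D array"),
      class = "sarcohab_input_error"
    )
  }
  x
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3 || !is.numeric(spacing) || any(!is.finite(spacing)) ||
    any(spacing <= 0)) {
    abort("spacing must be 3 positive finite numbers (mm)",
      class = "sarcohab_input_error"
    )
  }
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf(
    "<intensity_volume> %s, %s voxels, spacing %s mm\n",
    x$modality, paste(dim(x$voxels), collapse = "x"),
    paste(signif(x$spacing, 3), collapse = "x")
  ))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> %s voxels, %d foreground, spacing %s mm\n",
    paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
    paste(signif(x$spacing, 3), collapse = "x")
  ))
  invisible(x)
}

# ---- NIfTI IO ---------------------------------------------------------------

#' Read and write volumes and masks as NIfTI
#'
#' Volumes are stored as floating point, masks as unsigned 8-bit 0/1. Spacing
#' is taken from (written to) the NIfTI `pixdim` field. Orientation metadata
#' beyond spacing is ignored: volumes are assumed co-registered with their
#' masks.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Modality tag to attach on read.
#' @param volume,mask Objects to write.
#' @return `read_volume()`/`read_mask()` return the imaging object;
#'   the writers return `path` invisibly.
#' @export
read_volume <- function(path, modality = c("CT", "MRI")) {
  img <- RNifti::readNifti(path)
  intensity_volume(unclass(img)[, , , drop = FALSE],
    spacing = RNifti::pixdim(img)[1:3], modality = modality
  )
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(
    structure(volume$voxels, pixdim = volume$spacing),
    datatype = "double"
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(unclass(img)[, , , drop = FALSE] != 0, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(
    structure(array(as.integer(mask$voxels), dim(mask$voxels)),
      pixdim = mask$spacing
    ),
    datatype = "uint8"
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- Resampling -------------------------------------------------------------

# Cell-centred 1-D regrid: continuous 0-based input index for each output
# voxel centre, clamped to the grid (nearest-edge extrapolation).
regrid_axis <- function(n_in, s_in, n_out, s_out) {
  x_out <- (seq_len(n_out) - 0.5) * s_out
  pos <- x_out / s_in - 0.5
  pmin(pmax(pos, 0), n_in - 1)
}

# Interpolate a 3-D array along its first axis at continuous positions `pos`
# (0-based), linearly or by nearest neighbour.
interp_first_axis <- function(arr, pos, method) {
  d <- dim(arr)
  if (method == "nearest") {
    idx <- round(pos) + 1
    out <- arr[idx, , , drop = FALSE]
  } else {
    lo <- floor(pos)
    w <- pos - lo
    hi <- pmin(lo + 1, d[1] - 1)
    # first index varies fastest, so weights recycle correctly along axis 1
    out <- arr[lo + 1, , , drop = FALSE] * (1 - w) + arr[hi + 1, , , drop = FALSE] * w
  }
  out
}

resample_grid <- function(voxels, spacing, target_spacing, method) {
  d_in <- dim(voxels)
  d_out <- pmax(1L, as.integer(round(d_in * spacing / target_spacing)))
  out <- voxels
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    out <- aperm(out, perm)
    pos <- regrid_axis(d_in[ax], spacing[ax], d_out[ax], target_spacing[ax])
    out <- interp_first_axis(out, pos, method)
    out <- aperm(out, order(perm))
  }
  out
}

#' Resample a volume to a target (isotropic) spacing
#'
#' Trilinear interpolation on cell-centred voxel coordinates; each output grid
#' dimension is `round(input_dim * input_spacing / target_spacing)` (at least
#' 1). Values outside the input grid are clamped to the nearest edge voxel.
#' The default target reproduces the 1 x 1 x 1 mm analysis grid used
#' throughout the pipeline.
#'
#' @param volume An [intensity_volume()].
#' @param target_spacing Positive length-3 numeric, mm.
#' @return A resampled [intensity_volume()].
#' @export
resample_isotropic <- function(volume, target_spacing = c(1, 1, 1)) {
  check_spacing(target_spacing)
  if (identical(as.numeric(target_spacing), volume$spacing)) {
    return(volume)
  }
  vox <- resample_grid(volume$voxels, volume$spacing, target_spacing, "linear")
  intensity_volume(vox, target_spacing, volume$modality)
}

#' @rdname resample_isotropic
#' @param mask An [roi_mask()]. Masks use nearest-neighbour interpolation so
#'   the output stays binary; an empty resampled mask raises an empty-ROI
#'   error.
#' @export
resample_mask <- function(mask, target_spacing = c(1, 1, 1)) {
  check_spacing(target_spacing)
  if (identical(as.numeric(target_spacing), mask$spacing)) {
    return(mask)
  }
  vox <- resample_grid(
    array(as.numeric(mask$voxels), dim(mask$voxels)),
    mask$spacing, target_spacing, "nearest"
  )
  if (!any(vox != 0)) {
    warn("mask is empty after resampling")
  }
  roi_mask(vox != 0, target_spacing)
}

# ---- ROI extraction and cohort pooling --------------------------------------

#' Extract ROI voxel intensities
#'
#' Returns the intensities of foreground-mask voxels as a vector in the fixed
#' array storage order (first index fastest, third slowest), so repeated calls
#' and downstream splits are deterministic.
#'
#' @param volume An [intensity_volume()].
#' @param mask An [roi_mask()] with the same grid shape and spacing.
#' @return A numeric vector of length `sum(mask$voxels)`.
#' @export
extract_roi_intensities <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)) ||
    !isTRUE(all.equal(volume$spacing, mask$spacing))) {
    abort("volume and mask must share grid shape and spacing",
      class = "sarcohab_input_error"
    )
  }
  volume$voxels[mask$voxels]
}

#' Pool ROI intensities across a cohort
#'
#' Concatenates per-subject ROI voxel vectors into the global intensity vector
#' on which cohort-level cluster models are fitted, recording per-subject
#' index ranges. Only training-set subjects should be pooled; the derived
#' thresholds are then applied unchanged to validation subjects.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]) or any data frame
#'   with `subject_id`, `volume` and `mask` list-columns.
#' @return A `pooled_intensities` object: `values` (numeric vector),
#'   `offsets` (tibble with `subject_id`, `start`, `end`, 1-based inclusive),
#'   and `modality`.
#' @export
pool_cohort <- function(cohort) {
  if (nrow(cohort) < 1) {
    abort("at least one subject is required", class = "sarcohab_input_error")
  }
  mods <- unique(vapply(cohort$volume, function(v) v$modality, character(1)))
  if (length(mods) != 1) {
    abort("cannot pool mixed modalities", class = "sarcohab_input_error")
  }
  vecs <- purrr::map2(
    cohort$volume, cohort$mask,
    function(v, m) extract_roi_intensities(v, m)
  )
  len <- lengths(vecs)
  end <- cumsum(len)
  structure(
    list(
      values = unlist(vecs, use.names = FALSE),
      offsets = tibble::tibble(
        subject_id = cohort$subject_id,
        start = end - len + 1L,
        end = end
      ),
      modality = mods
    ),
    class = "pooled_intensities"
  )
}

#' @export
print.pooled_intensities <- function(x, ...) {
  cat(sprintf(
    "<pooled_intensities> %s, %d voxels from %d subjects\n",
    x$modality, length(x$values), nrow(x$offsets)
  ))
  invisible(x)
}

#' Per-subject median intensity scaling
#'
#' Optional cross-scanner standardisation, mainly for raw (uncalibrated)
#' T2-weighted MRI: each subject's volume is rescaled so its ROI median
#' matches the cohort median-of-medians. Off by default throughout the
#' pipeline; apply it to a cohort *before* pooling/classification so that
#' thresholds and features see the same scale.
#'
#' @param cohort A cohort tibble with `volume` and `mask` list-columns.
#' @return The cohort with rescaled volumes and the scale factors in a
#'   `median_scale` column.
#' @export
median_scale_cohort <- function(cohort) {
  med <- purrr::map2_dbl(
    cohort$volume, cohort$mask,
    function(v, m) median(extract_roi_intensities(v, m))
  )
  if (any(med <= 0)) {
    abort("median scaling needs positive ROI medians (use on MRI-like data)",
      class = "sarcohab_input_error"
    )
  }
  target <- median(med)
  scale <- target / med
  cohort$volume <- purrr::map2(cohort$volume, scale, function(v, s) {
    v$voxels <- v$voxels * s
    v
  })
  cohort$median_scale <- scale
  cohort
}

#' Split pooled intensities back into per-subject vectors
#'
#' @param pooled A `pooled_intensities` object.
#' @return A named list of numeric vectors, one per subject.
#' @export
pooled_segments <- function(pooled) {
  setNames(
    purrr::map2(
      pooled$offsets$start, pooled$offsets$end,
      function(s, e) pooled$values[s:e]
    ),
    pooled$offsets$subject_id
  )
}
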