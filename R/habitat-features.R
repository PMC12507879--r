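#' Per-subject habitat features
#'
#' Computes the six quantitative habitat parameters from a classified ROI:
#' mean intensity, volume (voxel count x voxel volume, i.e. mm^3 on the 1 mm
#' analysis grid) and volume percentage of the fat and muscle habitats.
#' Percentages are stored as fractions in `[0, 1]`. An empty habitat has a
#' missing (`NA`) mean — never 0, since 0 is a valid intensity — zero volume
#' and zero percentage.
#'
#' @param volume An [intensity_volume()].
#' @param mask An [roi_mask()] aligned with `volume`.
#' @param labels A `habitat_labels` array from [classify_voxels()], consistent
#'   with `mask`.
#' @param subject_id Identifier for the output row.
#' @return A one-row tibble: `subject_id`, `fat_mean`, `fat_volume`,
#'   `fat_percent`, `muscle_mean`, `muscle_volume`, `muscle_percent`.
#' @export
compute_habitat_features <- function(volume, mask, labels,
                                     subject_id = NA_character_) {
  n_roi <- sum(mask$voxels)
  if (n_roi == 0) {
    abort("empty ROI", class = "sarcohab_empty_roi_error")
  }
  lab <- as.integer(labels)[as.vector(mask$voxels)]
  if (length(lab) != n_roi || any(lab == 0L)) {
    abort("label map is inconsistent with the mask",
      class = "sarcohab_input_error"
    )
  }
  vals <- volume$voxels[mask$voxels]
  voxel_volume <- prod(volume$spacing)
  n_fat <- sum(lab == 2L)
  n_mus <- n_roi - n_fat
  tibble::tibble(
    subject_id = subject_id,
    fat_mean = if (n_fat > 0) mean(vals[lab == 2L]) else NA_real_,
    fat_volume = n_fat * voxel_volume,
    fat_percent = n_fat / n_roi,
    muscle_mean = if (n_mus > 0) mean(vals[lab == 1L]) else NA_real_,
    muscle_volume = n_mus * voxel_volume,
    muscle_percent = n_mus / n_roi
  )
}

#' Habitat features for every subject of a cohort
#'
#' Classifies each subject's ROI with a fitted cohort-level threshold and
#' computes the per-subject habitat features.
#'
#' @param cohort A cohort tibble with `subject_id`, `volume`, `mask` columns.
#' @param model A `cluster_model` from [fit_cluster_model()] (or a scalar
#'   threshold, in which case the cohort modality is used).
#' @return A tibble with one feature row per subject.
#' @export
habitat_features <- function(cohort, model) {
  purrr::pmap_dfr(
    list(cohort$subject_id, cohort$volume, cohort$mask),
    function(id, vol, msk) {
      labels <- classify_voxels(vol, msk, model)
      compute_habitat_features(vol, msk, labels, subject_id = id)
    }
  )
}

#' Join habitat features with subject covariates
#'
#' Produces the per-subject analysis table: habitat features renamed with a
#' `<modality>_<habitat>_<Parameter>` convention (e.g. `CT_fat_Mean`,
#' `CT_fat_Volume`, `CT_fat_Percent` and the muscle/MRI analogues) joined to
#' the subject record columns.
#'
#' @param features A feature tibble from [habitat_features()].
#' @param subjects A data frame with `subject_id` plus covariate/label
#'   columns (volume/mask/truth list-columns are dropped).
#' @param modality Prefix for the feature column names.
#' @return A tibble with one row per subject.
#' @export
feature_table <- function(features, subjects, modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  if (anyDuplicated(features$subject_id) || anyDuplicated(subjects$subject_id)) {
    abort("duplicate subject_id", class = "sarcohab_input_error")
  }
  renames <- c(
    fat_mean = paste0(modality, "_fat_Mean"),
    fat_volume = paste0(modality, "_fat_Volume"),
    fat_percent = paste0(modality, "_fat_Percent"),
    muscle_mean = paste0(modality, "_muscle_Mean"),
    muscle_volume = paste0(modality, "_muscle_Volume"),
    muscle_percent = paste0(modality, "_muscle_Percent")
  )
  feat <- dplyr::rename_with(
    features,
    function(nm) unname(renames[nm]),
    .cols = dplyr::all_of(names(renames))
  )
  subj <- tibble::as_tibble(subjects)
  subj <- subj[, !vapply(subj, is.list, logical(1)), drop = FALSE]
  dplyr::inner_join(subj, feat, by = "subject_id")
}
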