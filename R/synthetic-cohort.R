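#' Configure the synthetic cohort generator
#'
#' Builds the configuration for simulated cohorts of paraspinal-muscle ROIs
#' with known voxel-level muscle/fat ground truth and clinical covariates.
#' Each subject's ROI voxels are i.i.d. draws from a two-component Gaussian
#' intensity mixture whose fat weight is the subject's true fat fraction;
#' sarcopenia shifts the fat-fraction distribution upwards and mildly shrinks
#' the ROI. Component polarity follows the contrast physics of each modality:
#' on CT fat is hypodense (negative HU) relative to muscle, on
#' non-fat-suppressed T2-weighted MRI fat is hyperintense.
#'
#' Default intensities are a plausible HU scale for CT (muscle +50, fat -90,
#' SD 15) and an arbitrary T2w scale for MRI (muscle 300, fat 900, SD 120).
#' Per-subject scanner variation is an additive offset (`intensity_jitter_sd`)
#' plus, for MRI, a multiplicative log-normal gain (`gain_jitter_sdlog`)
#' emulating uncalibrated cross-scanner signal differences; the MRI defaults
#' are deliberately much larger than the CT ones, mirroring the weaker
#' intensity standardisation of raw T2w.
#'
#' @param modality `"CT"` or `"MRI"`.
#' @param n_non_sarcopenia,n_sarcopenia Group sizes (each >= 1).
#' @param roi_shape Voxel grid dimensions of each subject's volume.
#' @param fat_fraction_mean Length-2 numeric, mean true fat fraction for the
#'   non-sarcopenia and sarcopenia groups, each in `[0, 1]` with the
#'   sarcopenia mean strictly larger.
#' @param fat_fraction_sd SD of the per-subject fat fraction (draws are
#'   truncated to `[0, 1]`).
#' @param muscle_mean,fat_mean,component_sd Intensity parameters of the two
#'   mixture components; `NULL` selects the modality default.
#' @param intensity_jitter_sd Per-subject additive intensity offset SD;
#'   `NULL` selects the modality default (CT 3, MRI 60).
#' @param gain_jitter_sdlog SD of the per-subject log-normal intensity gain;
#'   `NULL` selects the modality default (CT 0, MRI 0.4).
#' @param roi_radius_frac Ellipsoid ROI radius as a fraction of each grid
#'   dimension.
#' @param roi_radius_jitter Relative uniform jitter applied independently to
#'   each ellipsoid radius (subject-to-subject anatomical variation).
#' @param sarcopenia_atrophy Radius shrink factor applied to sarcopenia
#'   subjects' ROIs (0.97 = ~9% compartment volume loss).
#' @param seed Master seed; all per-subject seeds derive from it.
#'
#' @return A `generator_config` object (a validated list).
#' @export
#' @examples
#' cfg <- generator_config("CT", n_non_sarcopenia = 3, n_sarcopenia = 2,
#'                         roi_shape = c(12, 12, 6), seed = 1)
generator_config <- function(modality = c("CT", "MRI"),
                             n_non_sarcopenia = 100,
                             n_sarcopenia = 100,
                             roi_shape = c(40, 40, 16),
                             fat_fraction_mean = c(0.15, 0.45),
                             fat_fraction_sd = 0.07,
                             muscle_mean = NULL,
                             fat_mean = NULL,
                             component_sd = NULL,
                             intensity_jitter_sd = NULL,
                             gain_jitter_sdlog = NULL,
                             roi_radius_frac = 0.42,
                             roi_radius_jitter = 0.10,
                             sarcopenia_atrophy = 0.97,
                             seed = 1L) {
  modality <- match.arg(modality)
  defaults <- switch(modality,
    CT = list(muscle = 50, fat = -90, sd = 15, jitter = 3, gain = 0),
    MRI = list(muscle = 300, fat = 900, sd = 120, jitter = 60, gain = 0.4)
  )
  cfg <- list(
    modality = modality,
    n_non_sarcopenia = as.integer(n_non_sarcopenia),
    n_sarcopenia = as.integer(n_sarcopenia),
    roi_shape = as.integer(roi_shape),
    fat_fraction_mean = as.numeric(fat_fraction_mean),
    fat_fraction_sd = as.numeric(fat_fraction_sd),
    muscle_mean = muscle_mean %||% defaults$muscle,
    fat_mean = fat_mean %||% defaults$fat,
    component_sd = component_sd %||% defaults$sd,
    intensity_jitter_sd = intensity_jitter_sd %||% defaults$jitter,
    gain_jitter_sdlog = gain_jitter_sdlog %||% defaults$gain,
    roi_radius_frac = roi_radius_frac,
    roi_radius_jitter = roi_radius_jitter,
    sarcopenia_atrophy = sarcopenia_atrophy,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$n_non_sarcopenia < 1 || cfg$n_sarcopenia < 1) {
    abort("both groups need at least one subject", class = "sarcohab_config_error")
  }
  if (length(cfg$roi_shape) != 3 || any(cfg$roi_shape < 4)) {
    abort("roi_shape must be 3 dimensions, each >= 4", class = "sarcohab_config_error")
  }
  ff <- cfg$fat_fraction_mean
  if (length(ff) != 2 || any(!is.finite(ff)) || any(ff < 0) || any(ff > 1)) {
    abort("fat_fraction_mean must be two fractions in [0, 1]",
      class = "sarcohab_config_error"
    )
  }
  if (ff[2] <= ff[1]) {
    abort("sarcopenia fat-fraction mean must exceed the non-sarcopenia mean",
      class = "sarcohab_config_error"
    )
  }
  if (cfg$fat_fraction_sd < 0) {
    abort("fat_fraction_sd must be >= 0", class = "sarcohab_config_error")
  }
  if (cfg$modality == "CT" && cfg$fat_mean >= cfg$muscle_mean) {
    abort("on CT the fat mean must lie below the muscle mean",
      class = "sarcohab_config_error"
    )
  }
  if (cfg$modality == "MRI" && cfg$fat_mean <= cfg$muscle_mean) {
    abort("on MRI the fat mean must lie above the muscle mean",
      class = "sarcohab_config_error"
    )
  }
  if (cfg$component_sd <= 0) {
    abort("component_sd must be > 0", class = "sarcohab_config_error")
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %s, n = %d + %d, grid %s, fat fraction %.2f / %.2f\n",
    x$modality, x$n_non_sarcopenia, x$n_sarcopenia,
    paste(x$roi_shape, collapse = "x"), x$fat_fraction_mean[1],
    x$fat_fraction_mean[2]
  ))
  invisible(x)
}

# Group-specific clinical covariate distributions (mean, sd), rows =
# non-sarcopenia / sarcopenia.
covariate_defaults <- list(
  age = list(mean = c(68.13, 71.65), sd = c(6.88, 7.01)),
  bmi = list(mean = c(24.99, 22.83), sd = c(3.40, 3.18)),
  albumin = list(mean = c(37.89, 35.90), sd = c(3.09, 3.32)),
  hemoglobin = list(mean = c(136.76, 130.77), sd = c(18.03, 16.31)),
  rbc = list(mean = c(4.50, 4.36), sd = c(0.54, 0.48))
)

#' Generate one synthetic subject
#'
#' Draws a subject record, an ellipsoidal ROI mask, ground-truth voxel tissue
#' labels and the intensity volume. Anatomy (fat fraction, ROI geometry,
#' tissue labels, covariates) is derived from `seed` alone, so the same
#' subject imaged on CT and MRI (same seed, different config modality) shares
#' its anatomy while the intensities differ.
#'
#' @param config A [generator_config()].
#' @param group 0 (non-sarcopenia) or 1 (sarcopenia).
#' @param seed Integer seed for this subject.
#' @param subject_id Identifier stored in the record.
#'
#' @return A list with `volume` ([intensity_volume()]), `mask` ([roi_mask()]),
#'   `record` (one-row tibble with covariates, label and `true_fat_fraction`)
#'   and `truth` (integer array: 0 outside, 1 muscle, 2 fat).
#' @export
generate_subject <- function(config, group, seed = config$seed,
                             subject_id = sprintf("S%04d", seed %% 10000L)) {
  stopifnot(inherits(config, "generator_config"))
  if (!group %in% c(0, 1)) {
    abort("group must be 0 or 1", class = "sarcohab_config_error")
  }
  g <- group + 1L
  dims <- config$roi_shape

  # anatomy stream: identical across modalities for the same seed
  anatomy <- with_seed(seed, {
    f <- rnorm(1, config$fat_fraction_mean[g], config$fat_fraction_sd)
    f <- min(1, max(0, f))
    radii <- config$roi_radius_frac * dims *
      runif(3, 1 - config$roi_radius_jitter, 1 + config$roi_radius_jitter)
    if (group == 1) radii <- radii * config$sarcopenia_atrophy
    covs <- lapply(covariate_defaults, function(d) {
      max(rnorm(1, d$mean[g], d$sd[g]), 0.01)
    })
    mask <- ellipsoid_mask(dims, radii)
    n_roi <- sum(mask)
    labels_fat <- runif(n_roi) < f
    list(f = f, covs = covs, mask = mask, labels_fat = labels_fat)
  })

  # intensity stream: modality-salted so CT/MRI intensities are independent
  vox <- with_seed(child_seed(seed, 0L, salt = match(config$modality, c("CT", "MRI"))), {
    gain <- exp(rnorm(1, 0, config$gain_jitter_sdlog))
    offset <- rnorm(1, 0, config$intensity_jitter_sd)
    n_roi <- length(anatomy$labels_fat)
    mu <- ifelse(anatomy$labels_fat, config$fat_mean, config$muscle_mean)
    rnorm(n_roi, mu * gain + offset, config$component_sd * gain)
  })

  background <- if (config$modality == "CT") -1000 else 0
  grid <- array(background, dims)
  grid[anatomy$mask] <- vox
  truth <- array(0L, dims)
  truth[anatomy$mask] <- ifelse(anatomy$labels_fat, 2L, 1L)

  record <- tibble::tibble(
    subject_id = subject_id,
    sarcopenia = as.integer(group),
    age = anatomy$covs$age,
    bmi = anatomy$covs$bmi,
    albumin = anatomy$covs$albumin,
    hemoglobin = anatomy$covs$hemoglobin,
    rbc = anatomy$covs$rbc,
    true_fat_fraction = anatomy$f
  )

  list(
    volume = intensity_volume(grid, c(1, 1, 1), config$modality),
    mask = roi_mask(anatomy$mask, c(1, 1, 1)),
    record = record,
    truth = truth
  )
}

ellipsoid_mask <- function(dims, radii) {
  centre <- (dims + 1) / 2
  ii <- (seq_len(dims[1]) - centre[1]) / radii[1]
  jj <- (seq_len(dims[2]) - centre[2]) / radii[2]
  kk <- (seq_len(dims[3]) - centre[3]) / radii[3]
  d2 <- outer(outer(ii^2, jj^2, `+`), kk^2, `+`)
  d2 <= 1
}

#' Generate a synthetic cohort
#'
#' Generates `n_non_sarcopenia + n_sarcopenia` subjects with per-subject seeds
#' derived reproducibly from the master seed, so the same configuration always
#' yields byte-identical cohorts (and identical downstream feature tables).
#'
#' @param config A [generator_config()].
#' @return A tibble of class `sarcohab_cohort`, one row per subject, with the
#'   record columns plus `volume`, `mask` and `truth` list-columns. The
#'   modality is stored in the `"modality"` attribute.
#' @export
#' @examples
#' cfg <- generator_config("CT", n_non_sarcopenia = 2, n_sarcopenia = 2,
#'                         roi_shape = c(10, 10, 6), seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort$sarcopenia
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  groups <- c(
    rep(0L, config$n_non_sarcopenia),
    rep(1L, config$n_sarcopenia)
  )
  subjects <- purrr::map(seq_along(groups), function(i) {
    generate_subject(config, groups[i],
      seed = child_seed(config$seed, i),
      subject_id = sprintf("S%04d", i)
    )
  })
  out <- dplyr::bind_rows(purrr::map(subjects, "record"))
  out$volume <- purrr::map(subjects, "volume")
  out$mask <- purrr::map(subjects, "mask")
  out$truth <- purrr::map(subjects, "truth")
  attr(out, "modality") <- config$modality
  class(out) <- c("sarcohab_cohort", class(out))
  out
}

#' Write a cohort to disk
#'
#' Writes each subject's volume and mask as NIfTI (`.nii.gz`), the subject
#' table as CSV (`subjects.csv`, columns `subject_id`, `sarcopenia`, `age`,
#' `bmi`, `albumin`, `hemoglobin`, `rbc`) and the generator configuration as
#' YAML (`config.yaml`).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param config The [generator_config()] used, written alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    write_volume(cohort$volume[[i]], file.path(dir, paste0(id, "_vol.nii.gz")))
    write_mask(cohort$mask[[i]], file.path(dir, paste0(id, "_mask.nii.gz")))
  }
  readr::write_csv(
    dplyr::select(
      tibble::as_tibble(cohort), "subject_id", "sarcopenia", "age", "bmi",
      "albumin", "hemoglobin", "rbc"
    ),
    file.path(dir, "subjects.csv")
  )
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
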