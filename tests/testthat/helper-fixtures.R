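# Small reusable fixtures. The default full-scale experiment is expensive, so
# it is computed once per test run and cached.

tiny_config <- function(modality = "CT", seed = 42L, ...) {
  generator_config(
    modality = modality, n_non_sarcopenia = 4, n_sarcopenia = 4,
    roi_shape = c(14, 14, 8), seed = seed, ...
  )
}

make_volume <- function(values, dims = NULL, spacing = c(1, 1, 1),
                        modality = "CT") {
  dims <- dims %||% dim(values)
  intensity_volume(array(values, dims), spacing, modality)
}

make_mask <- function(values, dims = NULL, spacing = c(1, 1, 1)) {
  dims <- dims %||% dim(values)
  roi_mask(array(values, dims), spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cache <- new.env(parent = emptyenv())

# The fixed-seed default-condition experiment shared by the acceptance tests:
# generator defaults (n = 100 + 100 per group, both modalities, all methods).
default_experiment <- function() {
  if (is.null(.cache$exp)) {
    .cache$exp <- suppressWarnings(run_experiment(run_config(seed = 1L)))
  }
  .cache$exp
}

default_ct_cohort <- function() {
  if (is.null(.cache$ct_cohort)) {
    .cache$ct_cohort <- generate_cohort(run_config(seed = 1L)$generators$CT)
  }
  .cache$ct_cohort
}
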