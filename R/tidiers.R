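#' Tidy a fitted cluster model
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return A tibble with one row per mixture component / centroid (empty for
#'   a pure Otsu model, which has no component parameters).
#' @export
tidy.cluster_model <- function(x, ...) {
  if (x$method == "gmm") {
    tibble::tibble(
      component = c("low", "high"),
      weight = x$gmm_weights,
      mean = x$gmm_means,
      variance = x$gmm_variances
    )
  } else if (x$method == "kmeans") {
    tibble::tibble(
      component = c("low", "high"),
      weight = NA_real_,
      mean = x$kmeans_centroids,
      variance = NA_real_
    )
  } else {
    tibble::tibble(
      component = character(0), weight = numeric(0),
      mean = numeric(0), variance = numeric(0)
    )
  }
}

#' @rdname tidy.cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    modality = x$modality,
    threshold = x$threshold,
    initial_boundary = x$initial_boundary,
    refined = x$refined,
    fat_is_lower = x$fat_is_lower,
    n_values = x$n_values,
    em_iterations = if (x$method == "gmm") length(x$loglik_trace) else NA_integer_,
    em_converged = if (x$method == "gmm") x$em_converged else NA
  )
}

#' Tidy a logistic model: term-level odds-ratio table
#'
#' @param x A `sarcohab_logistic`.
#' @param ... Unused.
#' @return A tibble with estimates, Wald statistics, odds ratios and 95% CIs.
#' @export
tidy.sarcohab_logistic <- function(x, ...) {
  x$terms
}

#' @rdname tidy.sarcohab_logistic
#' @export
glance.sarcohab_logistic <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    converged = x$converged,
    separation = x$separation,
    deviance = x$fit$deviance,
    null_deviance = x$fit$null.deviance,
    aic = x$fit$aic
  )
}

#' @export
tidy.sarcohab_stepwise <- function(x, ...) {
  tidy.sarcohab_logistic(x$final)
}

#' @export
glance.sarcohab_stepwise <- function(x, ...) {
  dplyr::bind_cols(
    glance.sarcohab_logistic(x$final),
    tibble::tibble(
      n_removed = length(x$removed),
      removed = paste(x$removed, collapse = ";")
    )
  )
}

#' One-row summary of a ROC evaluation
#'
#' @param x A `roc_summary`.
#' @param ... Unused.
#' @export
glance.roc_summary <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_low = x$ci[1], auc_high = x$ci[2],
    cutoff = x$cutoff, sensitivity = x$sensitivity,
    specificity = x$specificity, accuracy = x$accuracy, youden = x$youden
  )
}

#' @rdname glance.roc_summary
#' @export
tidy.roc_summary <- function(x, ...) {
  x$curve
}

#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_aucs), auc = x$fold_aucs)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    k = x$k, mean_auc = x$mean_auc,
    sd_auc = sd(x$fold_aucs), seed = x$seed
  )
}
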