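#' Plot a fitted cluster model over the pooled intensity histogram
#'
#' Shows the pooled intensity distribution with the derived muscle/fat
#' threshold (solid) and, if refinement was applied, the initial boundary
#' (dashed) and the flanking histogram peaks (dotted).
#'
#' @param object A `cluster_model`.
#' @param values The pooled intensities the model was fitted on (a
#'   `pooled_intensities` object or numeric vector).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_model <- function(object, values, ...) {
  if (inherits(values, "pooled_intensities")) values <- values$values
  df <- tibble::tibble(intensity = values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$intensity)) +
    ggplot2::geom_histogram(bins = object$n_bins, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("%s intensity", object$modality), y = "voxel count",
      title = sprintf("%s threshold = %.4g", object$method, object$threshold)
    ) +
    ggplot2::theme_minimal()
  if (isTRUE(object$refined)) {
    p <- p +
      ggplot2::geom_vline(
        xintercept = object$initial_boundary,
        colour = "firebrick", linetype = "dashed"
      ) +
      ggplot2::geom_vline(
        xintercept = object$peaks,
        colour = "steelblue", linetype = "dotted"
      )
  }
  p
}

#' Plot a ROC curve with its Youden-optimal operating point
#'
#' @param object A `roc_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_summary <- function(object, ...) {
  op <- tibble::tibble(
    fpr = 1 - object$specificity,
    tpr = object$sensitivity
  )
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = op, colour = "firebrick", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC %.3f (%.3f-%.3f)", object$auc, object$ci[1],
                      object$ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a habitat label map
#'
#' Muscle is drawn in blue, fat in red, background left white — the
#' conventional rendering of muscle/fat habitat maps.
#'
#' @param object A `habitat_labels` array from [classify_voxels()].
#' @param slice Index of the third-axis slice (default: middle).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.habitat_labels <- function(object, slice = NULL, ...) {
  d <- dim(object)
  slice <- slice %||% ceiling(d[3] / 2)
  sl <- object[, , slice]
  # first array index varies fastest, matching as.vector()
  df <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[1]))
  df$label <- factor(
    as.vector(sl),
    levels = 0:2, labels = c("outside", "muscle", "fat")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(outside = "white", muscle = "steelblue", fat = "firebrick")
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("habitat map, slice %d", slice)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}

#' Compare ROC curves across the models of an experiment
#'
#' @param experiment A `habitat_experiment`.
#' @param which `"validation"` (default) or `"train"`.
#' @return A ggplot overlaying one ROC curve per successful model.
#' @export
plot_roc_curves <- function(experiment, which = c("validation", "train")) {
  which <- match.arg(which)
  field <- paste0("roc_", which)
  curves <- purrr::map_dfr(experiment$results$detail, function(d) {
    if (d$status != "ok") return(NULL)
    dplyr::bind_cols(
      tibble::tibble(model = paste(d$method, d$modality, sep = "_")),
      d[[field]]$curve
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("%s ROC curves", which)) +
    ggplot2::theme_minimal()
}
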