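#' Intensity histogram
#'
#' Equal-width histogram over `[min(values), max(values)]`, the shared
#' representation for Otsu thresholding and peak detection.
#'
#' @param values Numeric vector of intensities.
#' @param n_bins Number of bins (default 256, the standard choice for Otsu).
#' @return A list with `edges` (length `n_bins + 1`), `counts`, `mids`.
#' @export
intensity_histogram <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || min(values) == max(values)) {
    abort("need at least two distinct finite values",
      class = "sarcohab_degenerate_error"
    )
  }
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(edges = edges, counts = counts, mids = (edges[-1] + edges[-(n_bins + 1)]) / 2)
}

#' Otsu threshold
#'
#' Exhaustive maximisation of the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over all interior bin boundaries
#' of the intensity histogram. Ties are broken by the smallest threshold.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Histogram bins.
#' @return The threshold (a bin boundary), as a scalar.
#' @export
#' @examples
#' otsu_threshold(c(rnorm(300, 0), rnorm(300, 10)))
otsu_threshold <- function(values, n_bins = 256L) {
  h <- intensity_histogram(values, n_bins)
  otsu_from_histogram(h$counts, h$edges)
}

otsu_from_histogram <- function(counts, edges) {
  B <- length(counts)
  mids <- (edges[-1] + edges[-(B + 1)]) / 2
  n <- sum(counts)
  cw <- cumsum(counts)
  cm <- cumsum(counts * mids)
  k <- seq_len(B - 1)
  w0 <- cw[k] / n
  w1 <- 1 - w0
  mu0 <- cm[k] / cw[k]
  mu1 <- (cm[B] - cm[k]) / (n - cw[k])
  crit <- w0 * w1 * (mu0 - mu1)^2
  crit[!is.finite(crit)] <- -Inf
  if (all(crit == -Inf)) {
    abort("degenerate histogram: all mass in one bin",
      class = "sarcohab_degenerate_error"
    )
  }
  edges[which.max(crit) + 1] # which.max keeps the first (smallest t) on ties
}

#' One-dimensional two-cluster k-means
#'
#' k-means++ initialisation followed by Lloyd iterations, with `n_restarts`
#' independent starts keeping the best within-cluster sum of squares. An
#' empty cluster is re-seeded at the point farthest from the other centroid.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param seed Integer seed controlling the random restarts.
#' @param n_restarts Number of k-means++ restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return A list: `centroids` (sorted ascending), `assignments` (1/2 index
#'   into the sorted centroids), `objective` (WCSS), `iterations`.
#' @export
kmeans_1d <- function(values, seed = 1L, n_restarts = 10L, max_iter = 300L) {
  x <- values[is.finite(values)]
  if (length(x) < 2 || min(x) == max(x)) {
    abort("need at least two distinct finite values",
      class = "sarcohab_degenerate_error"
    )
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      c1 <- x[sample.int(length(x), 1)]
      d2 <- (x - c1)^2
      c2 <- if (all(d2 == 0)) c1 else x[sample.int(length(x), 1, prob = d2)]
      cen <- c(c1, c2)
      iter <- 0L
      assign_old <- NULL
      repeat {
        iter <- iter + 1L
        assign_new <- ifelse(abs(x - cen[1]) <= abs(x - cen[2]), 1L, 2L)
        for (j in 1:2) {
          if (!any(assign_new == j)) {
            # re-seed an empty cluster at the farthest point
            far <- which.max(abs(x - cen[3 - j]))
            cen[j] <- x[far]
            assign_new[far] <- j
          }
        }
        cen <- c(mean(x[assign_new == 1]), mean(x[assign_new == 2]))
        if (identical(assign_new, assign_old) || iter >= max_iter) break
        assign_old <- assign_new
      }
      obj <- sum((x - cen[assign_new])^2)
      if (is.null(best) || obj < best$objective) {
        best <- list(centroids = cen, assignments = assign_new,
                     objective = obj, iterations = iter)
      }
    }
    ord <- order(best$centroids)
    list(
      centroids = best$centroids[ord],
      assignments = order(ord)[best$assignments],
      objective = best$objective,
      iterations = best$iterations
    )
  })
}

#' Two-component Gaussian mixture via EM
#'
#' Expectation-maximisation for a univariate two-component Gaussian mixture,
#' initialised from a k-means solution (means = centroids, weights and
#' variances from the k-means partition). Iterates until the relative
#' log-likelihood change falls below `tol` or `max_iter` is reached. Variances
#' are clamped at `var_floor` to prevent component collapse.
#'
#' @param values Numeric vector.
#' @param init Length-2 numeric: initial component means (k-means centroids),
#'   or a full [kmeans_1d()] result.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param var_floor Variance floor; defaults to `1e-6 * var(values)`.
#' @return A list: `weights`, `means`, `variances` (each length 2, means
#'   ascending), `loglik_trace` (non-decreasing), `iterations`, `converged`.
#' @export
gmm_em <- function(values, init, tol = 1e-6, max_iter = 500L, var_floor = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 2 || min(x) == max(x)) {
    abort("need at least two distinct finite values",
      class = "sarcohab_degenerate_error"
    )
  }
  var_floor <- var_floor %||% (1e-6 * var(x))
  if (is.list(init)) {
    mu <- init$centroids
    w <- c(mean(init$assignments == 1), mean(init$assignments == 2))
    v <- vapply(1:2, function(j) {
      xs <- x[init$assignments == j]
      if (length(xs) > 1) var(xs) else var(x) / 4
    }, numeric(1))
  } else {
    mu <- sort(as.numeric(init))
    w <- c(0.5, 0.5)
    v <- rep(var(x) / 4, 2)
  }
  w <- pmax(w, 1e-6)
  w <- w / sum(w)
  v <- pmax(v, var_floor)

  loglik <- -Inf
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    # E-step in log space for numerical stability
    l1 <- log(w[1]) + dnorm(x, mu[1], sqrt(v[1]), log = TRUE)
    l2 <- log(w[2]) + dnorm(x, mu[2], sqrt(v[2]), log = TRUE)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    if (any(!is.finite(lse))) {
      abort("non-finite likelihood in EM", class = "sarcohab_numeric_error")
    }
    ll <- sum(lse)
    trace <- c(trace, ll)
    r1 <- exp(l1 - lse)
    if (is.finite(loglik) && abs(ll - loglik) <= tol * abs(loglik)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    loglik <- ll
    # M-step
    n1 <- sum(r1)
    n2 <- length(x) - n1
    w <- c(n1, n2) / length(x)
    w <- pmax(w, 1e-10)
    w <- w / sum(w)
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    v <- c(sum(r1 * (x - mu[1])^2) / n1, sum((1 - r1) * (x - mu[2])^2) / n2)
    v <- pmax(v, var_floor)
  }
  ord <- order(mu)
  list(
    weights = w[ord], means = mu[ord], variances = v[ord],
    loglik_trace = trace, iterations = iter, converged = converged
  )
}

# Equal-posterior boundary of a two-component Gaussian mixture: the root of
# w1 N(t; m1, v1) = w2 N(t; m2, v2) lying between the means. Falls back to
# the midpoint when no root lies in range (e.g. near-identical components).
gmm_boundary <- function(weights, means, variances) {
  m1 <- means[1]; m2 <- means[2]
  v1 <- variances[1]; v2 <- variances[2]
  if (abs(m2 - m1) < sqrt(.Machine$double.eps) * (abs(m1) + abs(m2) + 1)) {
    return(mean(means))
  }
  # log w1 - ((t-m1)^2)/(2 v1) - log(sqrt(v1)) = log w2 - ((t-m2)^2)/(2 v2) - log(sqrt(v2))
  # rearranged as a t^2 + b t + cc = 0
  a <- 1 / v2 - 1 / v1
  b <- 2 * (m1 / v1 - m2 / v2)
  cc <- (m2^2 / v2 - m1^2 / v1) + log(v2 / v1) - 2 * log(weights[2] / weights[1])
  if (abs(a) < 1e-300) {
    # equal variances: linear equation
    t <- -cc / b
    if (t > min(m1, m2) && t < max(m1, m2)) return(t)
    return(mean(means))
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(mean(means))
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > min(m1, m2) & roots < max(m1, m2)]
  if (length(inside) == 0) return(mean(means))
  inside[1]
}

# Smoothed-histogram peak positions: centred moving average (window 5 bins),
# local maxima ranked by smoothed height.
histogram_peaks <- function(counts, mids, window = 5L) {
  k <- rep(1 / window, window)
  sm <- as.numeric(stats::filter(counts, k, sides = 2))
  sm[is.na(sm)] <- 0
  B <- length(sm)
  left <- c(-Inf, sm[-B])
  right <- c(sm[-1], -Inf)
  is_peak <- sm >= left & sm >= right & (sm > left | sm > right) & sm > 0
  tibble::tibble(position = mids[is_peak], height = sm[is_peak])
}

#' Fit a cohort-level cluster model and derive the muscle/fat threshold
#'
#' Fits the requested clustering of the pooled ROI intensities and derives a
#' scalar decision threshold: Otsu's threshold itself, the assignment-flip
#' boundary (centroid midpoint) for k-means, or the equal-posterior boundary
#' for the GMM (which is initialised from the k-means solution). The initial
#' boundary is then refined by re-running Otsu on the histogram restricted to
#' the closed interval between the two smoothed-histogram peaks flanking it;
#' if fewer than two flanking peaks are found the initial boundary is kept
#' with a warning.
#'
#' @param pooled A `pooled_intensities` object from [pool_cohort()] (or a bare
#'   numeric vector plus an explicit `modality`).
#' @param method `"otsu"`, `"kmeans"` or `"gmm"`.
#' @param n_bins Histogram bins for Otsu and for the refinement.
#' @param seed Seed for the stochastic k-means initialisation.
#' @param refine Apply the peak-restricted Otsu refinement (default `TRUE`).
#' @param modality Overrides the modality recorded in `pooled`.
#' @inheritParams gmm_em
#' @return A `cluster_model` object: the fitted parameters, the initial and
#'   final `threshold`, the flanking `peaks`, and `fat_is_lower` (the
#'   modality polarity used by [classify_voxels()]).
#' @export
fit_cluster_model <- function(pooled, method = c("otsu", "kmeans", "gmm"),
                              n_bins = 256L, seed = 1L, refine = TRUE,
                              tol = 1e-6, max_iter = 500L,
                              modality = NULL) {
  method <- match.arg(method)
  if (inherits(pooled, "pooled_intensities")) {
    values <- pooled$values
    modality <- modality %||% pooled$modality
  } else {
    values <- as.numeric(pooled)
    if (is.null(modality)) {
      abort("modality is required when passing a bare vector",
        class = "sarcohab_input_error"
      )
    }
  }
  fit <- list()
  initial <- switch(method,
    otsu = otsu_threshold(values, n_bins),
    kmeans = {
      fit$kmeans <- kmeans_1d(values, seed = seed)
      mean(fit$kmeans$centroids)
    },
    gmm = {
      fit$kmeans <- kmeans_1d(values, seed = seed)
      fit$gmm <- gmm_em(values, fit$kmeans, tol = tol, max_iter = max_iter)
      gmm_boundary(fit$gmm$weights, fit$gmm$means, fit$gmm$variances)
    }
  )

  threshold <- initial
  peaks <- NULL
  refined <- FALSE
  if (refine) {
    h <- intensity_histogram(values, n_bins)
    pk <- histogram_peaks(h$counts, h$mids)
    lo <- pk[pk$position < initial, ]
    hi <- pk[pk$position > initial, ]
    if (nrow(lo) > 0 && nrow(hi) > 0) {
      p_lo <- lo$position[which.max(lo$height)]
      p_hi <- hi$position[which.max(hi$height)]
      inside <- values[values >= p_lo & values <= p_hi]
      refined_t <- tryCatch(
        otsu_threshold(inside, n_bins),
        sarcohab_degenerate_error = function(e) NULL
      )
      if (!is.null(refined_t)) {
        threshold <- refined_t
        peaks <- c(p_lo, p_hi)
        refined <- TRUE
      }
    }
    if (!refined) {
      warn("fewer than two flanking histogram peaks; keeping unrefined boundary")
    }
  }

  structure(
    list(
      method = method,
      threshold = threshold,
      initial_boundary = initial,
      refined = refined,
      peaks = peaks,
      kmeans_centroids = fit$kmeans$centroids,
      gmm_weights = fit$gmm$weights,
      gmm_means = fit$gmm$means,
      gmm_variances = fit$gmm$variances,
      loglik_trace = fit$gmm$loglik_trace,
      em_converged = fit$gmm$converged,
      modality = modality,
      fat_is_lower = modality == "CT",
      n_bins = as.integer(n_bins),
      seed = as.integer(seed),
      n_values = length(values)
    ),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "<cluster_model> %s (%s), threshold %.4g%s, fitted on %d voxels\n",
    x$method, x$modality, x$threshold,
    if (x$refined) sprintf(" (refined from %.4g)", x$initial_boundary) else "",
    x$n_values
  ))
  invisible(x)
}

#' Classify ROI voxels into muscle and fat habitats
#'
#' Applies the scalar threshold with the modality polarity: on CT, intensity
#' `<= threshold` is fat (fat is hypodense); on non-fat-suppressed T2w MRI,
#' intensity `>= threshold` is fat (fat is hyperintense). Voxels outside the
#' mask are labelled 0.
#'
#' @param volume An [intensity_volume()].
#' @param mask An [roi_mask()] aligned with `volume`.
#' @param threshold Scalar threshold, or a `cluster_model` (its threshold and
#'   modality are used).
#' @param modality `"CT"` or `"MRI"`; defaults to the volume's tag.
#' @return A `habitat_labels` object: an integer array with 0 = outside,
#'   1 = muscle, 2 = fat, plus the spacing as an attribute.
#' @export
classify_voxels <- function(volume, mask, threshold, modality = NULL) {
  if (inherits(threshold, "cluster_model")) {
    modality <- modality %||% threshold$modality
    threshold <- threshold$threshold
  }
  modality <- modality %||% volume$modality
  if (is.null(modality) || !modality %in% c("CT", "MRI")) {
    abort("modality must be CT or MRI", class = "sarcohab_input_error")
  }
  if (!is.finite(threshold)) {
    abort("threshold must be finite", class = "sarcohab_input_error")
  }
  if (!identical(dim(volume$voxels), dim(mask$voxels))) {
    abort("volume and mask must share grid shape", class = "sarcohab_input_error")
  }
  fat <- if (modality == "CT") {
    volume$voxels <= threshold
  } else {
    volume$voxels >= threshold
  }
  labels <- array(0L, dim(volume$voxels))
  labels[mask$voxels] <- ifelse(fat[mask$voxels], 2L, 1L)
  structure(labels,
    spacing = volume$spacing, threshold = threshold,
    modality = modality, class = "habitat_labels"
  )
}

#' Write a habitat label map as NIfTI
#'
#' Integer codes: 0 outside, 1 muscle, 2 fat.
#'
#' @param labels A `habitat_labels` object from [classify_voxels()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_labelmap <- function(labels, path) {
  img <- RNifti::asNifti(
    structure(array(as.integer(labels), dim(labels)),
      pixdim = attr(labels, "spacing")
    ),
    datatype = "uint8"
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialise a fitted cluster model to JSON
#'
#' @param model A `cluster_model`.
#' @param path Output JSON path.
#' @export
write_cluster_model <- function(model, path) {
  keep <- model[!vapply(model, is.null, logical(1))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "cluster_model")
}
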