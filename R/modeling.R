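#' Stratified train/validation split
#'
#' Randomly partitions subjects into training and validation sets, stratified
#' by the outcome label: within each class, `round(train_fraction * n_class)`
#' subjects are assigned to training. The default 6:4 ratio matches the usual
#' retrospective design.
#'
#' @param subjects Data frame with `subject_id` and the label column.
#' @param train_fraction Fraction assigned to training within each class.
#' @param seed Integer seed; the same seed always yields the same partition.
#' @param label_col Name of the binary label column.
#' @return The input with an added `split` column (`"train"`/`"validation"`),
#'   as a tibble.
#' @export
split_cohort <- function(subjects, train_fraction = 0.6, seed = 1L,
                         label_col = "sarcopenia") {
  labels <- subjects[[label_col]]
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("each class needs at least two subjects", class = "sarcohab_input_error")
  }
  split <- rep("validation", nrow(subjects))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_train <- round(train_fraction * length(idx))
      split[sample(idx, n_train)] <- "train"
    }
  })
  out <- tibble::as_tibble(subjects)
  out$split <- split
  out
}

#' Compare a feature between two groups
#'
#' Continuous features are first screened for normality per group
#' (Lilliefors-corrected Kolmogorov-Smirnov); if both groups pass at
#' `alpha = 0.05` a Welch two-sample t-test is used, otherwise a
#' Mann-Whitney U test. Categorical features (factor/character/logical) use a
#' chi-square test without continuity correction, falling back to Fisher's
#' exact test when any expected cell count is below 5.
#'
#' @param data Data frame.
#' @param vars Character vector of feature columns to test.
#' @param group_col Binary grouping column.
#' @return A tibble: `variable`, `test`, `statistic`, `p_value`, and per-group
#'   mean/sd for continuous features. Constant features are flagged with
#'   `test = "degenerate"` and a missing p-value.
#' @export
group_compare <- function(data, vars, group_col = "sarcopenia") {
  g <- data[[group_col]]
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]
    gg <- g[ok]
    base <- tibble::tibble(
      variable = v, test = NA_character_,
      statistic = NA_real_, p_value = NA_real_,
      mean_0 = NA_real_, sd_0 = NA_real_, mean_1 = NA_real_, sd_1 = NA_real_
    )
    if (length(unique(gg)) < 2) {
      base$test <- "degenerate"
      return(base)
    }
    if (is.numeric(x) && length(unique(x)) > 2) {
      x0 <- x[gg == sort(unique(gg))[1]]
      x1 <- x[gg == sort(unique(gg))[2]]
      base$mean_0 <- mean(x0); base$sd_0 <- sd(x0)
      base$mean_1 <- mean(x1); base$sd_1 <- sd(x1)
      if (length(unique(x)) < 2 || sd(x0) == 0 || sd(x1) == 0) {
        base$test <- "degenerate"
        return(base)
      }
      normal <- function(z) {
        if (length(z) < 5) return(FALSE)
        nortest::lillie.test(z)$p.value > 0.05
      }
      if (normal(x0) && normal(x1)) {
        tt <- t.test(x0, x1)
        base$test <- "welch_t"
        base$statistic <- unname(tt$statistic)
        base$p_value <- tt$p.value
      } else {
        wt <- suppressWarnings(wilcox.test(x0, x1, exact = FALSE, correct = TRUE))
        base$test <- "mann_whitney"
        base$statistic <- unname(wt$statistic)
        base$p_value <- wt$p.value
      }
    } else {
      tab <- table(x, gg)
      if (nrow(tab) < 2) {
        base$test <- "degenerate"
        return(base)
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher.test(tab)
        base$test <- "fisher"
        base$p_value <- ft$p.value
      } else {
        ct <- chisq.test(tab, correct = FALSE)
        base$test <- "chi_square"
        base$statistic <- unname(ct$statistic)
        base$p_value <- ct$p.value
      }
    }
    base
  })
}

# ---- Logistic regression ----------------------------------------------------

#' Fit a logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood fit via iteratively reweighted least squares
#' (`stats::glm`), reporting per-predictor odds ratios with 95% Wald
#' confidence intervals and p-values. Quasi-complete separation (fitted
#' probabilities numerically 0/1) is flagged via `converged = FALSE` and a
#' diagnostic note rather than an error; a rank-deficient design (e.g. a
#' duplicated predictor) is an error.
#'
#' @param data Data frame containing outcome and predictors.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor columns.
#' @return A `sarcohab_logistic` object; see [tidy()] / [glance()] methods.
#' @export
fit_logistic <- function(data, outcome, predictors) {
  dat <- data[, c(outcome, predictors), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  f <- as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(f, family = binomial(), data = dat,
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge", msg)) {
        invokeRestart("muffleWarning") # reflected in the converged flag
      }
    }
  )
  if (any(is.na(coef(fit)))) {
    abort("rank-deficient design (collinear predictors)",
      class = "sarcohab_rank_error"
    )
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  terms <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(z),
    p_value = unname(p),
    odds_ratio = exp(unname(est)),
    or_low = exp(unname(est - 1.96 * se)),
    or_high = exp(unname(est + 1.96 * se))
  )
  structure(
    list(
      fit = fit,
      terms = terms,
      outcome = outcome,
      predictors = predictors,
      converged = fit$converged && !separation,
      separation = separation,
      n = nrow(dat)
    ),
    class = "sarcohab_logistic"
  )
}

#' @export
print.sarcohab_logistic <- function(x, ...) {
  cat(sprintf(
    "<sarcohab_logistic> %s ~ %s  (n = %d%s)\n",
    x$outcome, paste(x$predictors, collapse = " + "), x$n,
    if (!x$converged) ", NOT converged/separated" else ""
  ))
  print(x$terms)
  invisible(x)
}

#' Predicted probabilities from a fitted logistic model
#'
#' @param object A `sarcohab_logistic`.
#' @param newdata Data frame to score.
#' @param ... Unused.
#' @return Numeric vector of predicted sarcopenia probabilities.
#' @export
predict.sarcohab_logistic <- function(object, newdata, ...) {
  unname(predict(object$fit, newdata = newdata, type = "response"))
}

#' Univariate logistic screening
#'
#' Fits one single-predictor logistic regression per candidate and reports
#' the Wald odds-ratio table plus the likelihood-ratio p-value used for the
#' screening decision (`keep = p_lrt < alpha`). The likelihood-ratio test is
#' used for screening because Wald p-values collapse toward 1 under
#' quasi-complete separation, which strongly predictive imaging features
#' routinely produce.
#'
#' @inheritParams fit_logistic
#' @param alpha Screening significance level.
#' @return A tibble, one row per candidate predictor.
#' @export
screen_univariate <- function(data, outcome, predictors, alpha = 0.05) {
  purrr::map_dfr(predictors, function(v) {
    m <- tryCatch(fit_logistic(data, outcome, v), error = function(e) NULL)
    if (is.null(m)) {
      return(tibble::tibble(
        predictor = v, estimate = NA_real_, odds_ratio = NA_real_,
        or_low = NA_real_, or_high = NA_real_, p_wald = NA_real_,
        p_lrt = NA_real_, keep = FALSE
      ))
    }
    row <- m$terms[m$terms$term == v, ]
    dev0 <- m$fit$null.deviance
    dev1 <- m$fit$deviance
    p_lrt <- pchisq(dev0 - dev1, df = 1, lower.tail = FALSE)
    tibble::tibble(
      predictor = v,
      estimate = row$estimate,
      odds_ratio = row$odds_ratio,
      or_low = row$or_low,
      or_high = row$or_high,
      p_wald = row$p_value,
      p_lrt = p_lrt,
      keep = is.finite(p_lrt) && p_lrt < alpha
    )
  })
}

# Drop predictors that are exactly collinear with earlier ones (QR pivot on
# the design matrix), keeping first occurrences.
drop_aliased <- function(data, predictors) {
  if (length(predictors) < 2) return(predictors)
  X <- cbind(1, as.matrix(data[complete.cases(data[, predictors, drop = FALSE]),
                               predictors, drop = FALSE]))
  q <- qr(X)
  keep_idx <- sort(q$pivot[seq_len(q$rank)])
  keep_idx <- keep_idx[keep_idx > 1] - 1L
  predictors[keep_idx]
}

#' Backward stepwise logistic regression
#'
#' Starts from all candidate predictors and iteratively removes the predictor
#' with the largest Wald p-value while that p-value exceeds `alpha`, stopping
#' when all remaining predictors are significant or only one remains. The
#' removal order is recorded. The full pre-selection fit is kept alongside
#' the final model.
#'
#' @inheritParams fit_logistic
#' @param alpha Stay criterion for the Wald p-value.
#' @return A `sarcohab_stepwise` object: `final` and `full`
#'   (`sarcohab_logistic` fits), `removed` (character, in removal order).
#' @export
backward_stepwise <- function(data, outcome, predictors, alpha = 0.05) {
  if (length(predictors) < 1) {
    abort("no candidate predictors survived screening",
      class = "sarcohab_empty_model_error"
    )
  }
  full <- fit_logistic(data, outcome, predictors)
  current <- predictors
  removed <- character(0)
  fit <- full
  repeat {
    rows <- fit$terms[fit$terms$term %in% current, ]
    worst <- rows[which.max(rows$p_value), ]
    if (length(current) == 1 || worst$p_value <= alpha) break
    removed <- c(removed, worst$term)
    current <- setdiff(current, worst$term)
    fit <- fit_logistic(data, outcome, current)
  }
  structure(
    list(final = fit, full = full, removed = removed,
         predictors = fit$predictors, alpha = alpha),
    class = "sarcohab_stepwise"
  )
}

#' @export
print.sarcohab_stepwise <- function(x, ...) {
  cat(sprintf(
    "<sarcohab_stepwise> kept: %s%s\n",
    paste(x$predictors, collapse = ", "),
    if (length(x$removed)) paste0("; removed: ", paste(x$removed, collapse = ", "))
    else ""
  ))
  print(x$final$terms)
  invisible(x)
}

# ---- ROC / AUC --------------------------------------------------------------

#' AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney statistic (ties counted 1/2): the probability
#' that a random positive outranks a random negative. The 95% CI uses
#' DeLong's placement-based variance estimate, clamped to `[0, 1]`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return A list: `auc`, `ci` (length 2), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0) {
    abort("both classes must be present", class = "sarcohab_input_error")
  }
  # placements via ranks: V10_i = P(neg < pos_i) + 0.5 P(neg == pos_i)
  v10 <- vapply(pos, function(p) (sum(neg < p) + 0.5 * sum(neg == p)) / n,
    numeric(1)
  )
  v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / m,
    numeric(1)
  )
  auc <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)
  list(auc = auc, ci = ci, se = se, n_pos = m, n_neg = n)
}

confusion_counts <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  truth <- labels == 1
  list(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    fn = sum(!pred & truth), tn = sum(!pred & !truth)
  )
}

#' Youden index from sensitivity and specificity
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @return `sensitivity + specificity - 1`.
#' @export
youden_index <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Youden-optimal cutoff and operating metrics
#'
#' Candidate cutoffs are the midpoints between consecutive distinct sorted
#' scores plus -Inf/+Inf; a subject is called positive when its score is at
#' or above the cutoff. The cutoff maximising the Youden index
#' (sensitivity + specificity - 1) is selected, ties broken by higher
#' sensitivity and then by lower cutoff. Sensitivity, specificity and
#' accuracy follow the standard confusion-count formulas TP/(TP+FN),
#' TN/(TN+FP) and (TP+TN)/total.
#'
#' @inheritParams roc_auc
#' @return A list: `cutoff`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden`, `confusion` (TP/FP/FN/TN).
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(unique(labels)) < 2) {
    abort("both classes must be present", class = "sarcohab_input_error")
  }
  s <- sort(unique(scores))
  candidates <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- NULL
  for (ct in candidates) {
    cc <- confusion_counts(scores, labels, ct)
    sens <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 0
    spec <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else 0
    j <- youden_index(sens, spec)
    better <- is.null(best) || j > best$youden + 1e-12 ||
      (abs(j - best$youden) <= 1e-12 && sens > best$sensitivity + 1e-12)
    if (better) {
      best <- list(
        cutoff = ct, sensitivity = sens, specificity = spec,
        accuracy = (cc$tp + cc$tn) / length(scores),
        youden = j, confusion = cc
      )
    }
  }
  best
}

#' ROC summary: AUC, CI, Youden-optimal operating point
#'
#' Combines [roc_auc()] and [youden_cutoff()] into the standard model
#' evaluation row (AUC with 95% CI, cutoff, sensitivity, specificity,
#' accuracy, Youden index) and retains the full ROC curve for plotting.
#'
#' @inheritParams roc_auc
#' @return A `roc_summary` object; `glance()` returns it as a one-row tibble.
#' @export
roc_summary <- function(scores, labels) {
  a <- roc_auc(scores, labels)
  y <- youden_cutoff(scores, labels)
  labels <- as.integer(as.logical(labels) | labels == 1)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(cuts, function(ct) {
    cc <- confusion_counts(scores, labels, ct)
    tibble::tibble(
      fpr = cc$fp / max(cc$fp + cc$tn, 1),
      tpr = cc$tp / max(cc$tp + cc$fn, 1)
    )
  })
  structure(
    c(a[c("auc", "ci", "se", "n_pos", "n_neg")], y, list(curve = curve)),
    class = "roc_summary"
  )
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(
    "<roc_summary> AUC %.3f (95%% CI %.3f-%.3f), cutoff %.3g, sens %.3f, spec %.3f, Youden %.3f\n",
    x$auc, x$ci[1], x$ci[2], x$cutoff, x$sensitivity, x$specificity, x$youden
  ))
  invisible(x)
}

# ---- Cross-validation -------------------------------------------------------

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Five-fold cross-validated AUC of the full modelling recipe
#'
#' Stratified k-fold partition of the training set; in each fold the entire
#' recipe (univariate screening, aliased-column removal, backward stepwise
#' selection, logistic fit) is refit on the k-1 retained folds and the
#' held-out fold is scored. If no candidate survives screening within a fold,
#' the single candidate with the smallest screening p-value is used.
#'
#' @inheritParams fit_logistic
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param alpha Screening/stay significance level.
#' @return A `cv_result`: `fold_aucs`, `mean_auc`, `k`, `seed`.
#' @export
five_fold_cv <- function(data, outcome, predictors, k = 5L, seed = 1L,
                         alpha = 0.05) {
  labels <- data[[outcome]]
  if (any(table(labels) < k)) {
    abort(sprintf("each class needs at least %d subjects for %d-fold CV", k, k),
      class = "sarcohab_input_error"
    )
  }
  fold <- stratified_folds(labels, k, seed)
  aucs <- vapply(seq_len(k), function(i) {
    train <- data[fold != i, , drop = FALSE]
    test <- data[fold == i, , drop = FALSE]
    model <- fit_recipe(train, outcome, predictors, alpha = alpha)
    scores <- predict(model$final, test)
    keep <- !is.na(scores)
    roc_auc(scores[keep], test[[outcome]][keep])$auc
  }, numeric(1))
  structure(
    list(fold_aucs = aucs, mean_auc = mean(aucs), k = k, seed = as.integer(seed)),
    class = "cv_result"
  )
}

# screen -> drop aliased -> backward stepwise; shared by five_fold_cv and the
# pipeline orchestrator.
fit_recipe <- function(data, outcome, predictors, alpha = 0.05) {
  screen <- screen_univariate(data, outcome, predictors, alpha = alpha)
  kept <- screen$predictor[screen$keep]
  if (length(kept) == 0) {
    kept <- screen$predictor[which.min(screen$p_lrt)]
  }
  kept <- drop_aliased(data, kept)
  step <- backward_stepwise(data, outcome, kept, alpha = alpha)
  list(final = step$final, stepwise = step, screen = screen)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold mean AUC %.3f (folds: %s)\n",
    x$k, x$mean_auc, paste(sprintf("%.3f", x$fold_aucs), collapse = ", ")
  ))
  invisible(x)
}

# ---- ICC --------------------------------------------------------------------

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-measure, absolute-agreement ICC from the two-way random-effects
#' ANOVA mean squares:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares, `n` the number of subjects and `k` the number of
#' raters. Used to quantify intra-/inter-observer agreement of repeated ROI
#' measurements.
#'
#' @param ratings A complete numeric matrix, subjects x raters.
#' @return A list: `icc`, `ms` (the three mean squares), `n`, `k`.
#' @export
icc_two_way_random <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2 || anyNA(ratings)) {
    abort("need a complete matrix with >= 2 subjects and >= 2 raters",
      class = "sarcohab_input_error"
    )
  }
  long <- data.frame(
    score = as.vector(ratings),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- anova(aov(score ~ subject + rater, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr < .Machine$double.eps * mean(abs(ratings) + 1)) {
    warn("degenerate ratings: no between-subject variance")
  }
  list(
    icc = (msr - mse) / denom,
    ms = c(subjects = msr, raters = msc, error = mse),
    n = n, k = k
  )
}
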