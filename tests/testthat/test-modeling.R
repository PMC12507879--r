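subjects_fixture <- function(n0 = 30, n1 = 20, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("P%03d", 1:(n0 + n1)),
    sarcopenia = rep(c(0L, 1L), c(n0, n1)),
    x = rnorm(n0 + n1, mean = rep(c(0, 2), c(n0, n1))),
    noise = rnorm(n0 + n1)
  )
}

test_that("stratified split hits exact per-class counts and is reproducible", {
  subj <- subjects_fixture(6, 4)
  sp <- split_cohort(subj, 0.6, seed = 3)
  expect_equal(sum(sp$split == "train"), 6)
  expect_equal(sum(sp$split == "validation"), 4)
  expect_equal(sum(sp$split == "train" & sp$sarcopenia == 0), 4)
  expect_equal(sum(sp$split == "train" & sp$sarcopenia == 1), 2)
  expect_identical(split_cohort(subj, 0.6, seed = 3)$split, sp$split)
  expect_false(identical(split_cohort(subj, 0.6, seed = 4)$split, sp$split))
})

test_that("split is a disjoint exhaustive partition on random cohorts", {
  for (seed in 1:5) {
    subj <- subjects_fixture(sample(10:40, 1), sample(10:40, 1), seed)
    sp <- split_cohort(subj, 0.6, seed = seed)
    tr <- sp$subject_id[sp$split == "train"]
    va <- sp$subject_id[sp$split == "validation"]
    expect_length(intersect(tr, va), 0)
    expect_setequal(c(tr, va), subj$subject_id)
  }
})

test_that("identical groups give p = 1 under the Mann-Whitney test", {
  # heavily skewed values so the normality screen routes to Mann-Whitney
  x <- rep(c(1, 1.1, 1.2, 1.3, 1.15, 1.05, 1.25, 100), 2)
  d <- tibble::tibble(sarcopenia = rep(0:1, each = 8), v = x)
  res <- group_compare(d, "v")
  expect_equal(res$test, "mann_whitney")
  expect_equal(res$p_value, 1)
})

test_that("Welch t-test matches the closed-form computation on a toy sample", {
  x0 <- c(5.1, 4.9, 5.3, 5.0, 4.7)
  x1 <- c(6.0, 6.4, 5.8, 6.1, 6.2)
  d <- tibble::tibble(
    sarcopenia = rep(0:1, each = 5),
    v = c(x0, x1)
  )
  res <- group_compare(d, "v")
  expect_equal(res$test, "welch_t")
  tstat <- (mean(x0) - mean(x1)) /
    sqrt(var(x0) / length(x0) + var(x1) / length(x1))
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
})

test_that("chi-square statistic matches the hand computation 6.667", {
  d <- tibble::tibble(
    sarcopenia = rep(c(0L, 1L), c(30, 30)),
    cat = factor(c(rep("a", 20), rep("b", 10), rep("a", 10), rep("b", 20)))
  )
  res <- group_compare(d, "cat")
  expect_equal(res$test, "chi_square")
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
})

test_that("small expected cells fall back to Fisher's exact test", {
  d <- tibble::tibble(
    sarcopenia = rep(0:1, each = 8),
    cat = factor(c(rep("a", 7), "b", rep("a", 3), rep("b", 5)))
  )
  res <- group_compare(d, "cat")
  expect_equal(res$test, "fisher")
  expect_equal(res$p_value, fisher.test(table(d$cat, d$sarcopenia))$p.value)
})

test_that("constant features are flagged as degenerate", {
  d <- tibble::tibble(sarcopenia = rep(0:1, each = 10), v = rep(3.3, 20))
  res <- group_compare(d, "v")
  expect_equal(res$test, "degenerate")
  expect_true(is.na(res$p_value))
})

test_that("logistic OR on a 2x2 design equals the cross-product ratio", {
  d <- tibble::tibble(
    y = rep(c(1L, 1L, 0L, 0L), c(20, 10, 10, 20)),
    x = rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  )
  m <- fit_logistic(d, "y", "x")
  row <- m$terms[m$terms$term == "x", ]
  expect_equal(row$odds_ratio, 4.0, tolerance = 1e-6)
  expect_equal(row$estimate, log(4), tolerance = 1e-6)
})

test_that("perfectly balanced antisymmetric data gives intercept 0", {
  # P(y=1 | x) = 1 - P(y=1 | -x) by construction, and no separation
  d <- tibble::tibble(
    y = c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L),
    x = c(1, 1, 1, -1, -1, -1, 2, 2, 2, 2, -2, -2, -2, -2)
  )
  m <- fit_logistic(d, "y", "x")
  expect_equal(m$terms$estimate[m$terms$term == "(Intercept)"], 0,
    tolerance = 1e-8
  )
})

test_that("logistic coefficients match a direct likelihood optimiser", {
  set.seed(456)
  n <- 300
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 0.4 * x2))
  d <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  m <- fit_logistic(d, "y", c("x1", "x2"))
  negll <- function(b) {
    eta <- b[1] + b[2] * x1 + b[3] * x2
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), negll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(m$terms$estimate, opt$par, tolerance = 1e-6)
})

test_that("quasi-complete separation is flagged, not an error", {
  d <- tibble::tibble(
    y = rep(0:1, each = 20),
    x = c(rnorm(20, -10), rnorm(20, 10))
  )
  m <- fit_logistic(d, "y", "x")
  expect_false(m$converged)
  expect_true(m$separation)
  expect_true(all(is.finite(m$terms$estimate)))
})

test_that("duplicated predictor columns raise a rank-deficiency error", {
  d <- subjects_fixture()
  d$x_copy <- d$x
  expect_error(
    fit_logistic(d, "sarcopenia", c("x", "x_copy")),
    class = "sarcohab_rank_error"
  )
  expect_error(
    backward_stepwise(d, "sarcopenia", c("x", "x_copy")),
    class = "sarcohab_rank_error"
  )
})

test_that("stepwise keeps a single strong predictor unchanged", {
  d <- subjects_fixture(200, 200, seed = 2)
  st <- backward_stepwise(d, "sarcopenia", "x")
  expect_identical(st$predictors, "x")
  expect_length(st$removed, 0)
})

test_that("stepwise removes a pure-noise predictor (n = 500)", {
  set.seed(10)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x))
  d <- tibble::tibble(y = y, x = x, noise = rnorm(n))
  st <- backward_stepwise(d, "y", c("x", "noise"))
  expect_identical(st$predictors, "x")
  expect_identical(st$removed, "noise")
  # every retained predictor is significant
  kept <- st$final$terms[st$final$terms$term %in% st$predictors, ]
  expect_true(all(kept$p_value <= 0.05))
})

test_that("univariate screening keeps informative and drops null predictors", {
  d <- subjects_fixture(150, 150, seed = 8)
  sc <- screen_univariate(d, "sarcopenia", c("x", "noise"))
  expect_true(sc$keep[sc$predictor == "x"])
  expect_false(sc$keep[sc$predictor == "noise"])
})

test_that("AUC handles perfect separation, pure ties, and enumerates pairs", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.6, 0.5, 0.9), c(0, 0, 1, 1))$auc, 0.75)
})

test_that("AUC equals all-pairs enumeration on random small score sets", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    scores <- round(runif(n), 2) # rounding induces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(44)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a)
})

test_that("DeLong AUC and CI agree with pROC", {
  set.seed(90)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, plogis(scores))
  labels[1:2] <- c(0, 1)
  mine <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  # pROC uses the same DeLong variance; quantile constant differs in the
  # 4th decimal (1.96 vs qnorm(0.975))
  expect_equal(mine$ci, ref_ci[c(1, 3)], tolerance = 1e-3)
})

test_that("Youden metrics at a degenerate cutoff follow the printed formulas", {
  # TP=5, FN=0, TN=0, FP=5 at a cutoff below every score
  scores <- c(1:5 / 10, 6:10 / 10)
  labels <- rep(0:1, each = 5)
  cc <- sarcohab:::confusion_counts(scores, labels, cutoff = -Inf)
  expect_equal(cc$tp, 5)
  expect_equal(cc$fp, 5)
  sens <- cc$tp / (cc$tp + cc$fn)
  spec <- cc$tn / (cc$tn + cc$fp)
  expect_equal(sens, 1.0)
  expect_equal(spec, 0.0)
  expect_equal((cc$tp + cc$tn) / 10, 0.5)
})

test_that("Youden cutoff equals brute-force maximisation on random scores", {
  set.seed(73)
  for (rep in 1:30) {
    n <- sample(6:25, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    got <- youden_cutoff(scores, labels)
    want <- oracle_youden(scores, labels)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden, want$j)
    # internal consistency with the reported confusion counts
    cc <- got$confusion
    expect_equal(
      got$youden,
      cc$tp / (cc$tp + cc$fn) + cc$tn / (cc$tn + cc$fp) - 1
    )
  }
})

test_that("five-fold CV partitions are stratified, exhaustive and seeded", {
  labels <- rep(c(0, 1), c(60, 40))
  f1 <- sarcohab:::stratified_folds(labels, 5, seed = 9)
  expect_equal(as.vector(table(f1)), rep(20, 5))
  for (i in 1:5) {
    expect_equal(sum(labels == 1 & f1 == i), 8)
  }
  expect_identical(sarcohab:::stratified_folds(labels, 5, seed = 9), f1)
})

test_that("CV on perfectly separable features reaches AUC 1 in every fold", {
  d <- tibble::tibble(
    y = rep(0:1, each = 25),
    x = c(rnorm(25, -20), rnorm(25, 20))
  )
  cv <- suppressWarnings(five_fold_cv(d, "y", "x", seed = 2))
  expect_equal(cv$fold_aucs, rep(1, 5))
  expect_equal(cv$mean_auc, 1)
  cv2 <- suppressWarnings(five_fold_cv(d, "y", "x", seed = 2))
  expect_identical(cv$fold_aucs, cv2$fold_aucs)
})

test_that("ICC is 1 for identical raters and matches a hand ANOVA", {
  r <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  # aov warns about F-tests on a perfect fit; only the mean squares are used
  expect_equal(suppressWarnings(icc_two_way_random(r))$icc, 1)

  # 4x2 toy matrix: second rater = first + noise; hand-computed mean squares
  m <- cbind(c(10, 12, 14, 16), c(10.5, 11.5, 14.5, 15.5))
  n <- 4; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - msr * (n - 1) - msc * (k - 1)) / ((n - 1) * (k - 1))
  want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  got <- icc_two_way_random(m)
  expect_equal(got$icc, want, tolerance = 1e-12)
  expect_equal(unname(got$ms), c(msr, msc, mse), tolerance = 1e-12)
})

test_that("a constant rater against a varying one yields ICC near zero", {
  m <- cbind(rep(5, 6), c(1, 9, 2, 8, 3, 7))
  got <- icc_two_way_random(m)
  expect_lt(abs(got$icc), 0.35)
  expect_lt(got$icc, 0.5)
})

test_that("youden_index is sensitivity + specificity - 1", {
  expect_equal(youden_index(0.962, 0.993), 0.955)
  expect_equal(youden_index(1, 0), 0)
})
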