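test_that("Otsu separates two point masses and errors on constant input", {
  vals <- c(rep(0, 500), rep(10, 500))
  t <- otsu_threshold(vals, 256)
  expect_gt(t, 0)
  expect_lt(t, 10)
  expect_equal(sum(vals <= t), 500)
  expect_error(otsu_threshold(rep(3, 100)), class = "sarcohab_degenerate_error")
})

test_that("Otsu equals the exhaustive bin-boundary search on random samples", {
  set.seed(101)
  for (rep in 1:25) {
    vals <- c(rnorm(100, 0, 1), rnorm(100, 10, 1))
    expect_identical(otsu_threshold(vals, 256), oracle_otsu(vals, 256))
    # also at a coarser binning
    expect_identical(otsu_threshold(vals, 64), oracle_otsu(vals, 64))
  }
})

test_that("Otsu threshold is affine-equivariant up to one bin width", {
  set.seed(7)
  vals <- c(rnorm(400, 0, 1), rnorm(400, 8, 1))
  t0 <- otsu_threshold(vals, 256)
  a <- 2.5
  b <- -40
  t1 <- otsu_threshold(a * vals + b, 256)
  bin_width <- a * diff(range(vals)) / 256
  expect_lt(abs(t1 - (a * t0 + b)), bin_width + 1e-9)
})

test_that("k-means recovers the exact split of {1,2,9,10}", {
  km <- kmeans_1d(c(1, 2, 9, 10), seed = 1)
  expect_equal(km$centroids, c(1.5, 9.5))
  expect_equal(km$assignments, c(1L, 1L, 2L, 2L))
})

test_that("k-means is translation-equivariant", {
  set.seed(5)
  vals <- c(rnorm(60, 0), rnorm(60, 6))
  k1 <- kmeans_1d(vals, seed = 4)
  k2 <- kmeans_1d(vals + 123.5, seed = 4)
  expect_equal(k2$centroids, k1$centroids + 123.5, tolerance = 1e-9)
})

test_that("k-means with 10 restarts attains the brute-force optimum (n <= 50)", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    vals <- rnorm(n, mean = sample(c(0, 4), n, replace = TRUE))
    km <- kmeans_1d(vals, seed = rep, n_restarts = 10)
    opt <- oracle_kmeans_split(vals)
    expect_lte(km$objective, opt$objective * (1 + 1e-9))
  }
})

test_that("k-means matches stats::kmeans on a well-separated sample", {
  set.seed(77)
  vals <- c(rnorm(500, -90, 15), rnorm(500, 50, 15))
  km <- kmeans_1d(vals, seed = 1)
  ref <- kmeans(vals, centers = 2, nstart = 10)
  expect_equal(km$centroids, sort(as.numeric(ref$centers)), tolerance = 1e-6)
})

test_that("EM recovers the generating mixture from 20k draws", {
  set.seed(2024)
  vals <- c(rnorm(12000, -90, 15), rnorm(8000, 50, 15))
  km <- kmeans_1d(vals, seed = 1)
  g <- gmm_em(vals, km)
  expect_true(g$converged)
  expect_lt(abs(g$means[1] - (-90)), 2)
  expect_lt(abs(g$means[2] - 50), 2)
  expect_lt(abs(g$weights[1] - 0.6), 0.02)
  expect_lt(abs(g$weights[2] - 0.4), 0.02)
})

test_that("EM log-likelihood is monotone non-decreasing on every run", {
  set.seed(404)
  for (rep in 1:10) {
    vals <- c(
      rnorm(300, runif(1, -100, -50), runif(1, 5, 25)),
      rnorm(300, runif(1, 20, 80), runif(1, 5, 25))
    )
    g <- gmm_em(vals, kmeans_1d(vals, seed = rep))
    expect_true(all(diff(g$loglik_trace) >= -1e-10))
  }
})

test_that("EM on a single Gaussian stays finite and collapses sensibly", {
  set.seed(55)
  vals <- rnorm(2000, 5, 2)
  g <- gmm_em(vals, init = c(4, 6))
  expect_true(all(is.finite(c(g$weights, g$means, g$variances))))
  # either both means near the sample mean, or one weight near the floor
  near_mean <- all(abs(g$means - mean(vals)) < 1)
  one_dead <- min(g$weights) < 0.05
  expect_true(near_mean || one_dead)
})

test_that("EM agrees with mclust on a two-component fixture", {
  suppressPackageStartupMessages(library(mclust))
  set.seed(99)
  vals <- c(rnorm(3000, -90, 15), rnorm(2000, 50, 15))
  g <- gmm_em(vals, kmeans_1d(vals, seed = 1), tol = 1e-9)
  ref <- Mclust(vals, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(g$means), sort(as.numeric(ref$parameters$mean)),
    tolerance = 0.1
  )
  expect_equal(sort(g$weights), sort(as.numeric(ref$parameters$pro)),
    tolerance = 0.01
  )
})

test_that("equal-weight equal-variance GMM boundary is the midpoint", {
  b <- gmm_boundary(c(0.5, 0.5), c(-90, 50), c(225, 225))
  expect_equal(b, -20, tolerance = 1e-9)
  # matches the numeric density-crossing oracle for unequal weights too
  b2 <- gmm_boundary(c(0.3, 0.7), c(-90, 50), c(225, 225))
  expect_equal(
    b2,
    oracle_mixture_boundary(c(0.3, 0.7), c(-90, 50), c(15, 15)),
    tolerance = 0.01
  )
})

test_that("k-means-derived initial boundary is the centroid midpoint", {
  m <- fit_cluster_model(c(1, 2, 9, 10),
    method = "kmeans", refine = FALSE,
    modality = "CT", n_bins = 8
  )
  expect_equal(m$initial_boundary, 5.5)
  expect_equal(m$threshold, 5.5)
})

test_that("refined threshold stays within one bin width of unrestricted Otsu
           on clean bimodal data", {
  set.seed(300)
  vals <- c(rnorm(40000, -90, 15), rnorm(40000, 50, 15))
  bin_width <- diff(range(vals)) / 256
  t_plain <- otsu_threshold(vals, 256)
  for (met in c("otsu", "kmeans", "gmm")) {
    m <- fit_cluster_model(vals, method = met, modality = "CT", seed = 2)
    expect_true(m$refined)
    expect_lt(abs(m$threshold - t_plain), bin_width + 1e-9)
  }
})

test_that("classification applies the modality polarity", {
  v <- make_volume(seq(1, 24), c(4, 3, 2))
  msk <- make_mask(array(TRUE, c(4, 3, 2)))
  ct <- classify_voxels(v, msk, threshold = 0, modality = "CT")
  expect_true(all(ct[msk$voxels] == 1L)) # all above threshold -> muscle on CT
  v_m <- make_volume(seq(1, 24), c(4, 3, 2), modality = "MRI")
  mri <- classify_voxels(v_m, msk, threshold = 0)
  expect_true(all(mri[msk$voxels] == 2L)) # all above threshold -> fat on MRI
})

test_that("classification equals the elementwise comparison oracle", {
  set.seed(9)
  v <- make_volume(rnorm(4 * 4 * 3, 0, 50), c(4, 4, 3))
  keep <- array(runif(48) > 0.3, c(4, 4, 3))
  keep[2, 2, 2] <- TRUE
  msk <- make_mask(keep)
  t <- 5
  lab <- classify_voxels(v, msk, t, "CT")
  for (k in 1:3) for (j in 1:4) for (i in 1:4) {
    expected <- if (!keep[i, j, k]) 0L else if (v$voxels[i, j, k] <= t) 2L else 1L
    expect_identical(lab[i, j, k], expected)
  }
})

test_that("raising the CT threshold never decreases the fat count", {
  set.seed(21)
  v <- make_volume(rnorm(6 * 6 * 4, 0, 30), c(6, 6, 4))
  msk <- make_mask(array(TRUE, c(6, 6, 4)))
  counts <- vapply(seq(-60, 60, by = 10), function(t) {
    sum(classify_voxels(v, msk, t, "CT") == 2L)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("boundary-equal intensities go to fat on both modalities", {
  v <- make_volume(rep(5, 8), c(2, 2, 2))
  msk <- make_mask(array(TRUE, c(2, 2, 2)))
  expect_true(all(classify_voxels(v, msk, 5, "CT") == 2L))
  v_m <- make_volume(rep(5, 8), c(2, 2, 2), modality = "MRI")
  expect_true(all(classify_voxels(v_m, msk, 5, "MRI") == 2L))
})

test_that("cluster models serialise to JSON and back", {
  set.seed(1)
  vals <- c(rnorm(2000, -90, 15), rnorm(2000, 50, 15))
  m <- fit_cluster_model(vals, method = "gmm", modality = "CT", seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(m, path)
  back <- read_cluster_model(path)
  expect_equal(back$threshold, m$threshold, tolerance = 1e-12)
  expect_equal(back$gmm_means, m$gmm_means, tolerance = 1e-12)
  expect_identical(back$method, m$method)
})
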