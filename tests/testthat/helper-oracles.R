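# Independent brute-force oracles used to cross-check the implementations.
# These deliberately use naive loops and direct definitions.

# Exhaustive Otsu: between-class variance evaluated with explicit loops at
# every interior boundary of the equal-width histogram.
oracle_otsu <- function(values, n_bins = 256L) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf
  best_t <- NA_real_
  for (k in 1:(n_bins - 1)) {
    n0 <- sum(counts[1:k])
    n1 <- sum(counts[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / (n0 + n1)
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    crit <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (crit > best) {
      best <- crit
      best_t <- edges[k + 1]
    }
  }
  best_t
}

# Optimal 1-D 2-means: every optimal solution is a contiguous split of the
# sorted data, so enumerate all n-1 splits.
oracle_kmeans_split <- function(values) {
  x <- sort(values)
  n <- length(x)
  best <- Inf
  best_cen <- NULL
  for (s in 1:(n - 1)) {
    lo <- x[1:s]
    hi <- x[(s + 1):n]
    wcss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wcss < best) {
      best <- wcss
      best_cen <- c(mean(lo), mean(hi))
    }
  }
  list(objective = best, centroids = best_cen)
}

# AUC by all-pairs enumeration (ties counted 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Brute-force Youden maximisation over all candidate cutoffs, with the
# tie-break: higher sensitivity, then lower cutoff.
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- NULL
  for (ct in cands) {
    pred <- scores >= ct
    tp <- sum(pred & labels == 1)
    fn <- sum(!pred & labels == 1)
    tn <- sum(!pred & labels == 0)
    fp <- sum(pred & labels == 0)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(cutoff = ct, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Equal-posterior boundary of a two-component Gaussian mixture (weights,
# means, sds), solved numerically on a fine grid between the means.
oracle_mixture_boundary <- function(w, means, sds) {
  grid <- seq(min(means), max(means), length.out = 200001)
  d1 <- w[1] * dnorm(grid, means[1], sds[1])
  d2 <- w[2] * dnorm(grid, means[2], sds[2])
  grid[which.min(abs(d1 - d2))]
}
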