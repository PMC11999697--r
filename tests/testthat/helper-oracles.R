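# Independent pure-R oracles. These deliberately use naive enumeration /
# exhaustive scans so they share no code with the package's recursions.

# Log-likelihood by brute-force summation over all K^T state paths.
oracle_loglik <- function(x, means, sigma2, A, pi0) {
  K <- length(means)
  T_ <- length(x)
  paths <- expand.grid(rep(list(seq_len(K)), T_))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- as.integer(paths[r, ])
    lp <- log(pi0[p[1]]) + dnorm(x[1], means[p[1]], sqrt(sigma2), log = TRUE)
    if (T_ > 1) {
      for (t in 2:T_) {
        lp <- lp + log(A[p[t - 1], p[t]]) +
          dnorm(x[t], means[p[t]], sqrt(sigma2), log = TRUE)
      }
    }
    total <- total + exp(lp)
  }
  log(total)
}

# Best path by exhaustive enumeration; ties resolved toward the
# lexicographically smallest path (matching the per-step lower-index rule
# for the strict maxima used in the fixtures).
oracle_viterbi <- function(x, means, sigma2, A, pi0) {
  K <- length(means)
  T_ <- length(x)
  grid <- expand.grid(rep(list(seq_len(K)), T_))
  # order rows lexicographically so the first maximum is the tie-rule path
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  best_lp <- -Inf
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    p <- as.integer(grid[r, ])
    lp <- log(pi0[p[1]]) + dnorm(x[1], means[p[1]], sqrt(sigma2), log = TRUE)
    if (T_ > 1) {
      for (t in 2:T_) {
        lp <- lp + log(A[p[t - 1], p[t]]) +
          dnorm(x[t], means[p[t]], sqrt(sigma2), log = TRUE)
      }
    }
    if (lp > best_lp + 1e-12) {
      best_lp <- lp
      best <- p
    }
  }
  list(path = best, loglik = best_lp)
}

# Exhaustive single-split change point: the split frame (first frame of
# the right segment) maximizing the two-sample t statistic.
oracle_change_point <- function(x, min_segment = 5L) {
  n <- length(x)
  best <- list(frame = NA_integer_, score = -Inf)
  for (f in (min_segment + 1L):(n - min_segment + 1L)) {
    a <- x[1:(f - 1L)]
    b <- x[f:n]
    sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2L))
    sc <- abs(mean(b) - mean(a)) / max(sp * sqrt(1 / length(a) + 1 / length(b)), 1e-12)
    if (sc > best$score) best <- list(frame = f, score = sc, delta = mean(b) - mean(a))
  }
  best
}
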