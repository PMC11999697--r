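#' Gaussian kernel density of apparent-FRET values
#'
#' Composite histograms of apparent FRET efficiency are compiled as Gaussian
#' kernel density estimates with a fixed bandwidth (default 0.04 FRET
#' units, the kernel SD) on a fixed grid spanning [-0.2, 1.2] with 512
#' points, wide enough that unclamped noisy efficiencies remain
#' representable. The curve is renormalized so its trapezoidal integral
#' over the grid is 1.
#'
#' @param values Numeric vector of apparent FRET efficiencies (>= 1 finite
#'   value).
#' @param bandwidth Kernel SD in FRET units (default 0.04).
#' @param grid_limits,grid_n Evaluation grid (defaults [-0.2, 1.2], 512).
#' @return An object of class `smfret_density`: list with `grid`, `density`,
#'   `bandwidth`, `n_points`.
#' @export
kde_density <- function(values, bandwidth = 0.04, grid_limits = c(-0.2, 1.2),
                        grid_n = 512L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop_data("kde_density needs at least one finite value")
  check_scalar(bandwidth, "bandwidth", lower = 0, closed_lower = FALSE)
  d <- density(values, bw = bandwidth, kernel = "gaussian",
               from = grid_limits[1L], to = grid_limits[2L], n = grid_n)
  y <- d$y / trapezoid(d$x, d$y)
  structure(list(grid = d$x, density = y, bandwidth = bandwidth,
                 n_points = length(values)),
            class = "smfret_density")
}

trapezoid <- function(x, y) {
  n <- length(y)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

#' One-dimensional Gaussian mixture fit
#'
#' EM for a K-component Gaussian mixture with per-component variances,
#' used to quantify the composite apparent-FRET distribution produced by
#' the HMM analysis. When `init` is a fitted HMM (or `smfret_fit`), the
#' mixture is initialized from its state means and occupancies, which makes
#' the mixture fit a refinement of the HMM solution rather than an
#' independent local search; otherwise initialization uses evenly spaced
#' quantiles. Deterministic given inputs; components are relabeled in
#' decreasing order of mean on exit.
#'
#' @param values Pooled apparent FRET efficiencies (n >= 10 K).
#' @param K Number of mixture components.
#' @param init Optional [hmm_model()] or `smfret_fit` used for
#'   initialization.
#' @param seed Kept for interface symmetry; the fit is deterministic.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param variance_floor Lower bound for component variances.
#' @return An object of class `smfret_gmm`: `n_components`, `weights`,
#'   `means`, `variances`, `loglik`, `n_params` (= 3K - 1), `n`, `bic`.
#' @export
fit_gmm <- function(values, K, init = NULL, seed = 1L, tol = 1e-8,
                    max_iter = 500L, variance_floor = 1e-8) {
  values <- values[is.finite(values)]
  K <- check_count(K, "K", lower = 1L)
  n <- length(values)
  if (n < 10L * K) {
    stop_data("need at least %d values to fit %d components (have %d)",
              10L * K, K, n)
  }
  if (inherits(init, "smfret_fit")) {
    mu <- init$model$means
    w <- init$occupancy
    v <- rep(init$model$shared_variance, K)
  } else if (inherits(init, "smfret_hmm")) {
    mu <- init$means
    w <- stationary_dist(init$transition_matrix)
    v <- rep(init$shared_variance, K)
  } else {
    mu <- sort(as.numeric(quantile(values, (seq_len(K) - 0.5) / K, names = FALSE)),
               decreasing = TRUE)
    if (K > 1L && any(diff(mu) == 0)) mu <- mu + (K:1 - (K + 1) / 2) * 1e-8
    w <- rep(1 / K, K)
    v <- rep(max(var(values) / K, variance_floor), K)
  }
  if (length(mu) != K) stop_invalid("init model has %d states, need %d", length(mu), K)
  w <- pmax(w, 1e-6)
  w <- w / sum(w)
  v <- pmax(v, variance_floor)

  ll_prev <- -Inf
  ll <- -Inf
  for (iter in seq_len(max_iter)) {
    logp <- vapply(seq_len(K), function(k) {
      log(w[k]) + dnorm(values, mu[k], sqrt(v[k]), log = TRUE)
    }, numeric(n))
    m <- logp[cbind(seq_len(n), max.col(logp, ties.method = "first"))]
    p <- exp(logp - m)
    rs <- rowSums(p)
    ll <- sum(m + log(rs))
    r <- p / rs
    nk <- colSums(r)
    w <- nk / n
    mu <- as.numeric(crossprod(r, values)) / nk
    v <- vapply(seq_len(K), function(k) {
      sum(r[, k] * (values - mu[k])^2) / nk[k]
    }, numeric(1))
    v <- pmax(v, variance_floor)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) / (abs(ll_prev) + .Machine$double.eps) < tol) break
    ll_prev <- ll
  }
  ord <- order(mu, decreasing = TRUE)
  p_params <- 3L * K - 1L
  fit <- structure(list(n_components = K, weights = w[ord], means = mu[ord],
                        variances = v[ord], loglik = ll, n_params = p_params,
                        n = n, bic = NA_real_),
                   class = "smfret_gmm")
  fit$bic <- bic(fit, n)
  fit
}

#' @export
print.smfret_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, loglik = %.2f, BIC = %.2f (n = %d)\n",
              x$n_components, x$loglik, x$bic, x$n))
  cat("  means  :", paste(sprintf("%.3f", x$means), collapse = " "), "\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Bayesian Information Criterion of a mixture fit
#'
#' `BIC = p * ln(n) - 2 * loglik`, with `p = 3K - 1` free parameters for a
#' K-component Gaussian mixture (K means, K variances, K - 1 free weights).
#' Lower is better; the criterion is minimized at the number of states that
#' describes the data without overfitting.
#'
#' @param fit An `smfret_gmm`, or a list with `loglik` and `n_params`.
#' @param n Sample size (defaults to the fit's own `n`).
#' @return Numeric BIC value.
#' @export
bic <- function(fit, n = fit$n) {
  check_scalar(n, "n", lower = 1)
  fit$n_params * log(n) - 2 * fit$loglik
}
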