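#' K-state Gaussian hidden Markov model with shared variance
#'
#' The emission model is one-dimensional Gaussian on the apparent FRET
#' efficiency: state k emits `N(means[k], shared_variance)` with a single
#' variance common to all states. One transition matrix and one initial
#' distribution are shared by all trajectories of a condition. By package
#' convention state 1 is the highest-FRET state (means sorted in decreasing
#' order after every fit), matching the R, R', (R*'), R* naming from high to
#' low FRET.
#'
#' @param means Numeric vector of state means (decreasing order).
#' @param shared_variance Emission variance common to all states (>= the
#'   variance floor, 1e-6).
#' @param transition_matrix K x K row-stochastic per-frame matrix.
#' @param initial_dist Length-K probability vector.
#' @return An object of class `smfret_hmm`.
#' @export
hmm_model <- function(means, shared_variance, transition_matrix, initial_dist) {
  k <- length(means)
  if (k < 1L) stop_invalid("model must have at least one state")
  if (any(!is.finite(means))) stop_invalid("means must be finite")
  if (k > 1L && any(diff(means) > 0)) {
    stop_invalid("means must be sorted in decreasing order (state 1 = highest FRET)")
  }
  check_scalar(shared_variance, "shared_variance", lower = 1e-6)
  transition_matrix <- as.matrix(transition_matrix)
  if (nrow(transition_matrix) != k) stop_invalid("transition_matrix must be %d x %d", k, k)
  check_stochastic_matrix(transition_matrix, "transition_matrix")
  if (length(initial_dist) != k) stop_invalid("initial_dist must have length %d", k)
  check_simplex(initial_dist, "initial_dist")
  structure(list(n_states = k, means = as.numeric(means),
                 shared_variance = shared_variance,
                 transition_matrix = unname(transition_matrix),
                 initial_dist = as.numeric(initial_dist)),
            class = "smfret_hmm")
}

#' @export
print.smfret_hmm <- function(x, ...) {
  cat(sprintf("smFRET HMM: %d states, sigma = %.4f\n",
              x$n_states, sqrt(x$shared_variance)))
  cat("  means:", paste(sprintf("%.3f", x$means), collapse = " "), "\n")
  cat("  A diag:", paste(sprintf("%.3f", diag(x$transition_matrix)), collapse = " "), "\n")
  invisible(x)
}

#' EM fitting tolerances for the global HMM
#'
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param variance_floor Lower bound on the shared variance, in FRET^2
#'   (default 1e-6).
#' @param n_restarts Number of EM starts; restart seeds are derived from the
#'   master seed, the best final log-likelihood wins, ties go to the lowest
#'   restart index (default 1: a single deterministic quantile start).
#' @return An object of class `smfret_hmm_config`.
#' @export
hmm_config <- function(tol = 1e-6, max_iter = 1000L, variance_floor = 1e-6,
                       n_restarts = 1L) {
  structure(list(tol = check_scalar(tol, "tol", lower = 0, closed_lower = FALSE),
                 max_iter = check_count(max_iter, "max_iter", lower = 1L),
                 variance_floor = check_scalar(variance_floor, "variance_floor",
                                               lower = 0, closed_lower = FALSE),
                 n_restarts = check_count(n_restarts, "n_restarts", lower = 1L)),
            class = "smfret_hmm_config")
}

pool_eapp <- function(trajectories) {
  stopifnot(length(trajectories) >= 1L)
  unlist(lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "smfret_fret"))
    tr$e_app
  }), use.names = FALSE)
}

#' Deterministic initial model from pooled quantiles
#'
#' State means are placed at the K evenly spaced quantiles (levels
#' `(k - 0.5) / K`) of the pooled apparent-FRET values, the shared variance
#' at the pooled variance divided by K (at least the variance floor), the
#' transition matrix at 0.95 on the diagonal with uniform off-diagonal
#' mass, and the initial distribution uniform.
#'
#' @param trajectories List of [fret_trajectory()].
#' @param K Number of states.
#' @param seed Unused by the default deterministic initialization; kept so
#'   restart schemes can derive perturbed starts.
#' @param variance_floor Lower bound on the shared variance.
#' @return An [hmm_model()].
#' @export
init_model <- function(trajectories, K, seed = 1L, variance_floor = 1e-6) {
  K <- check_count(K, "K", lower = 1L)
  pooled <- pool_eapp(trajectories)
  if (length(pooled) < 10L * K) {
    stop_data("need at least %d pooled frames to initialize %d states (have %d)",
              10L * K, K, length(pooled))
  }
  means <- as.numeric(quantile(pooled, probs = (seq_len(K) - 0.5) / K,
                               names = FALSE))
  means <- sort(means, decreasing = TRUE)
  if (K > 1L && any(diff(means) == 0)) {
    # degenerate pooled distribution: break ties by a tiny deterministic spread
    means <- means + (K:1 - (K + 1) / 2) * 1e-8
  }
  v <- max(var(pooled) / K, variance_floor)
  if (!is.finite(v)) v <- variance_floor
  A <- matrix(if (K > 1L) 0.05 / (K - 1L) else 0, K, K)
  diag(A) <- if (K > 1L) 0.95 else 1
  hmm_model(means, v, A, rep(1 / K, K))
}

#' Forward-backward state posteriors for one trajectory
#'
#' Scaled forward-backward recursions; the per-frame emission likelihoods
#' are rescaled in log space so underflow is impossible for any trajectory
#' length.
#'
#' @param trajectory A [fret_trajectory()].
#' @param model An [hmm_model()].
#' @return List with `gamma` (T x K state posteriors, rows summing to 1),
#'   `xi` (K x K expected transition counts summed over frames), and
#'   `loglik`.
#' @export
forward_backward <- function(trajectory, model) {
  stopifnot(inherits(trajectory, "smfret_fret"), inherits(model, "smfret_hmm"))
  if (any(!is.finite(trajectory$e_app))) stop_invalid("trajectory contains non-finite values")
  cpp_forward_backward(trajectory$e_app, model$means, model$shared_variance,
                       model$transition_matrix, model$initial_dist)
}

#' Total log-likelihood of a set of trajectories under a model
#'
#' @param trajectories List of [fret_trajectory()].
#' @param model An [hmm_model()].
#' @return Sum of per-trajectory forward log-likelihoods (additive over
#'   disjoint trajectory sets).
#' @export
model_loglik <- function(trajectories, model) {
  sum(vapply(trajectories, function(tr) forward_backward(tr, model)$loglik,
             numeric(1)))
}

relabel_descending <- function(means, A, pi0, extra = NULL) {
  ord <- order(means, decreasing = TRUE)
  out <- list(means = means[ord], A = A[ord, ord, drop = FALSE], pi = pi0[ord],
              order = ord)
  if (!is.null(extra)) out$extra <- extra[ord]
  out
}

em_once <- function(trajectories, model, config) {
  n_traj <- length(trajectories)
  loglik_trajectory <- numeric(0)
  converged <- FALSE
  floored <- FALSE
  K <- model$n_states
  occupancy <- rep(1 / K, K)
  for (iter in seq_len(config$max_iter)) {
    ll <- 0
    pi_acc <- numeric(K)
    xi_acc <- matrix(0, K, K)
    ng <- numeric(K)
    sx <- numeric(K)
    sx2 <- numeric(K)
    for (tr in trajectories) {
      fb <- cpp_forward_backward(tr$e_app, model$means, model$shared_variance,
                                 model$transition_matrix, model$initial_dist)
      ll <- ll + fb$loglik
      g <- fb$gamma
      pi_acc <- pi_acc + g[1L, ]
      xi_acc <- xi_acc + fb$xi
      ng <- ng + colSums(g)
      sx <- sx + as.numeric(crossprod(g, tr$e_app))
      sx2 <- sx2 + as.numeric(crossprod(g, tr$e_app^2))
    }
    loglik_trajectory <- c(loglik_trajectory, ll)
    if (iter > 1L) {
      prev <- loglik_trajectory[iter - 1L]
      if (abs(ll - prev) / (abs(prev) + .Machine$double.eps) < config$tol) {
        converged <- TRUE
      }
    }
    # M step
    pi_new <- pi_acc / n_traj
    A_new <- model$transition_matrix
    rs <- rowSums(xi_acc)
    for (i in seq_len(K)) if (rs[i] > 0) A_new[i, ] <- xi_acc[i, ] / rs[i]
    mu_new <- model$means
    nz <- ng > 1e-12
    mu_new[nz] <- sx[nz] / ng[nz]
    v_new <- sum(sx2 - 2 * mu_new * sx + mu_new^2 * ng) / sum(ng)
    if (!is.finite(v_new) || v_new < config$variance_floor) {
      v_new <- config$variance_floor
      floored <- TRUE
    }
    occupancy <- ng / sum(ng)
    model <- structure(list(n_states = K, means = mu_new,
                            shared_variance = v_new,
                            transition_matrix = A_new, initial_dist = pi_new),
                       class = "smfret_hmm")
    if (converged) break
  }
  list(model = model, loglik_trajectory = loglik_trajectory,
       n_iterations = length(loglik_trajectory), converged = converged,
       variance_floored = floored, occupancy = occupancy)
}

# Deterministic alternative start: state means at the K tallest local
# maxima of the pooled kernel density (bandwidth 0.04). Quantile placement
# can miss a sparsely populated state when the pooled distribution is very
# skewed (e.g. a 5% active-state population); density peaks land on every
# well-separated mode regardless of its weight.
kde_peak_means <- function(pooled, K) {
  d <- kde_density(pooled, bandwidth = 0.04)
  y <- d$density
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n],
               FALSE)
  px <- d$grid[is_peak]
  ph <- y[is_peak]
  px <- px[order(ph, decreasing = TRUE)]
  if (length(px) >= K) return(sort(px[seq_len(K)], decreasing = TRUE))
  fill <- as.numeric(quantile(pooled, (seq_len(K) - 0.5) / K, names = FALSE))
  for (f in fill) {
    if (length(px) >= K) break
    if (!length(px) || min(abs(px - f)) > 1e-6) px <- c(px, f)
  }
  sort(px[seq_len(K)], decreasing = TRUE)
}

#' Fit a global shared-variance HMM to all trajectories of a condition
#'
#' Baum-Welch with sufficient statistics accumulated jointly across all
#' trajectories: every molecule contributes an independent chain started
#' from the shared initial distribution, and one transition matrix, one set
#' of state means, and a single pooled emission variance are re-estimated
#' from the pooled posteriors. Iterates until the relative log-likelihood
#' change falls below `config$tol` or `config$max_iter` is reached; states
#' are relabeled in decreasing order of mean on exit.
#'
#' Three deterministic starts are always evaluated -- the pooled-quantile
#' initialization of [init_model()], a density-peak initialization that
#' places the state means on the K tallest modes of the pooled kernel
#' density, and an evenly spaced initialization between the 2nd and 98th
#' pooled percentiles -- and the start with the best final log-likelihood
#' wins (ties go to the earlier start). Quantile placement tracks the
#' occupancy-weighted distribution and can starve a sparsely populated
#' state; the other two starts cover skewed and shoulder-merged
#' distributions. `config$n_restarts > 1` adds further perturbed starts
#' with seeds derived from `seed`.
#'
#' @param trajectories List of [fret_trajectory()] (>= 1; pooled frames must
#'   be >= 10 K).
#' @param K Number of states.
#' @param config An [hmm_config()].
#' @param seed Master seed for restart derivation (the default single start
#'   is deterministic).
#' @return An object of class `smfret_fit`: list with `model`
#'   ([hmm_model()]), `loglik_trajectory` (one total log-likelihood per
#'   iteration, non-decreasing), `n_iterations`, `converged`,
#'   `n_trajectories`, `n_frames`, `occupancy` (posterior state occupancy),
#'   `variance_floored`.
#' @export
em_fit <- function(trajectories, K, config = hmm_config(), seed = 1L) {
  K <- check_count(K, "K", lower = 1L)
  if (!length(trajectories)) stop_data("em_fit needs at least one trajectory")
  base <- init_model(trajectories, K, seed, config$variance_floor)
  runs <- list(em_once(trajectories, base, config))
  pooled <- pool_eapp(trajectories)
  starts <- list(kde_peak_means(pooled, K))
  if (K > 1L) {
    q <- quantile(pooled, c(0.02, 0.98), names = FALSE)
    starts <- c(starts, list(sort(seq(q[1L], q[2L], length.out = K),
                                  decreasing = TRUE)))
  }
  for (st in starts) {
    if (max(abs(st - base$means)) > 1e-9) {
      m <- base
      m$means <- st
      runs[[length(runs) + 1L]] <- em_once(trajectories, m, config)
    }
  }
  if (config$n_restarts > 1L) {
    pooled_sd <- sd(pooled)
    for (r in 2:config$n_restarts) {
      pert <- with_seed(derive_seed(seed, r), rnorm(K, 0, 0.25 * pooled_sd))
      m <- base
      m$means <- sort(base$means + pert, decreasing = TRUE)
      runs[[length(runs) + 1L]] <- em_once(trajectories, m, config)
    }
  }
  final_ll <- vapply(runs, function(r) max(r$loglik_trajectory), numeric(1))
  best <- runs[[which.max(final_ll)]]
  lab <- relabel_descending(best$model$means, best$model$transition_matrix,
                            best$model$initial_dist, best$occupancy)
  model <- hmm_model(lab$means, best$model$shared_variance, lab$A, lab$pi)
  structure(list(model = model, loglik_trajectory = best$loglik_trajectory,
                 n_iterations = best$n_iterations, converged = best$converged,
                 n_trajectories = length(trajectories),
                 n_frames = sum(vapply(trajectories, function(tr) tr$n_frames,
                                       numeric(1))),
                 occupancy = lab$extra,
                 variance_floored = best$variance_floored),
            class = "smfret_fit")
}

#' @export
print.smfret_fit <- function(x, ...) {
  cat(sprintf("smFRET global fit: K = %d, %d trajectories / %d frames, %d EM iterations (%s)\n",
              x$model$n_states, x$n_trajectories, x$n_frames, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$model)
  invisible(x)
}

#' Most likely state path of a trajectory
#'
#' Viterbi decoding under the fitted model; ties at every backtracking step
#' are broken toward the lower state index.
#'
#' @param trajectory A [fret_trajectory()].
#' @param model An [hmm_model()].
#' @return An object of class `smfret_path`: list with `trace_id`, `states`
#'   (integer labels in `1:K`), `path_loglik` (joint log-probability of the
#'   path and the observations).
#' @export
viterbi <- function(trajectory, model) {
  stopifnot(inherits(trajectory, "smfret_fret"), inherits(model, "smfret_hmm"))
  if (any(!is.finite(trajectory$e_app))) stop_invalid("trajectory contains non-finite values")
  v <- cpp_viterbi(trajectory$e_app, model$means, model$shared_variance,
                   model$transition_matrix, model$initial_dist)
  structure(list(trace_id = trajectory$trace_id,
                 states = as.integer(v$path) + 1L,
                 path_loglik = v$loglik),
            class = "smfret_path")
}

#' Decode every trajectory of a condition
#'
#' @param trajectories List of [fret_trajectory()].
#' @param model An [hmm_model()].
#' @return List of [viterbi()] paths, aligned with `trajectories`.
#' @export
viterbi_all <- function(trajectories, model) {
  lapply(trajectories, viterbi, model = model)
}
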