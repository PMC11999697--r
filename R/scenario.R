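#' Generative scenario for synthetic smFRET trajectories
#'
#' A `scenario_spec` is the generative twin of the hidden Markov model used
#' for inference: `n_states` conformational states with apparent-FRET means
#' `state_means`, a shared Gaussian emission standard deviation
#' `shared_sigma` (FRET units), a per-frame row-stochastic transition
#' matrix, an initial state distribution, and the camera frame interval.
#'
#' @param name Label for the scenario (e.g. `"apo-CXCR4"`).
#' @param state_means Numeric vector of apparent-FRET state means in (0, 1),
#'   in strictly monotone order (the package labels state 1 as the highest
#'   FRET state after every fit, so presets list means in decreasing order).
#' @param transition_matrix K x K row-stochastic matrix of per-frame state
#'   transition probabilities.
#' @param initial_dist Length-K probability vector for the first frame;
#'   defaults to the stationary distribution of `transition_matrix`, so that
#'   simulated occupancies are unbiased at any trace length.
#' @param shared_sigma Emission standard deviation in FRET units, common to
#'   all states (default 0.08).
#' @param frame_interval Frame interval in seconds (default 0.1, i.e. 100 ms
#'   camera integration).
#' @return An object of class `smfret_scenario`.
#' @seealso [scenario_presets()], [simulate_experiment()]
#' @export
scenario_spec <- function(name, state_means, transition_matrix,
                          initial_dist = NULL, shared_sigma = 0.08,
                          frame_interval = 0.1) {
  if (!is.character(name) || length(name) != 1L) {
    stop_invalid("scenario name must be a single string")
  }
  k <- length(state_means)
  if (k < 1L || k > 6L) stop_invalid("n_states must be in [1, 6] (got %d)", k)
  if (any(!is.finite(state_means)) || any(state_means <= 0) ||
      any(state_means >= 1)) {
    stop_invalid("state_means must lie strictly inside (0, 1)")
  }
  d <- diff(state_means)
  if (k > 1L && !(all(d > 0) || all(d < 0))) {
    stop_invalid("state_means must be in strictly monotone order")
  }
  if (k > 1L && min(abs(d)) <= 2 * .Machine$double.eps) {
    stop_invalid("state_means must be pairwise distinct")
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (nrow(transition_matrix) != k) {
    stop_invalid("transition_matrix must be %d x %d", k, k)
  }
  check_stochastic_matrix(transition_matrix, "transition_matrix")
  if (is.null(initial_dist)) {
    initial_dist <- stationary_dist(transition_matrix)
  }
  if (length(initial_dist) != k) stop_invalid("initial_dist must have length %d", k)
  check_simplex(initial_dist, "initial_dist")
  check_scalar(shared_sigma, "shared_sigma", lower = 0)
  check_scalar(frame_interval, "frame_interval", lower = 0, closed_lower = FALSE)
  structure(
    list(name = name, n_states = k, state_means = as.numeric(state_means),
         shared_sigma = shared_sigma,
         transition_matrix = unname(transition_matrix),
         initial_dist = as.numeric(initial_dist),
         frame_interval = frame_interval),
    class = "smfret_scenario")
}

#' @export
print.smfret_scenario <- function(x, ...) {
  cat(sprintf("smFRET scenario '%s': %d states, sigma = %.3g, dt = %.3g s\n",
              x$name, x$n_states, x$shared_sigma, x$frame_interval))
  cat("  state means:", paste(sprintf("%.2f", x$state_means), collapse = " "), "\n")
  cat("  stationary :",
      paste(sprintf("%.3f", stationary_dist(x$transition_matrix)), collapse = " "), "\n")
  invisible(x)
}

#' Channel noise, contamination, and photobleaching parameters
#'
#' Describes everything the camera adds on top of the ideal anti-correlated
#' donor/acceptor pair: total photon flux, additive per-channel Gaussian
#' noise, donor bleed-through into the acceptor channel, constant background
#' offsets, and per-frame photobleaching hazards. The bleach frame is drawn
#' from the geometric law implied by the hazards, truncated to
#' `[pre_bleach_frames_min, n_frames - post_bleach_frames_min]` so that every
#' simulated molecule retains a usable pre-bleach segment and a post-bleach
#' baseline, mirroring the molecules that survive screening in a real
#' experiment.
#'
#' @param total_intensity Mean summed photon counts per frame (arbitrary
#'   units; default 1000).
#' @param channel_noise_sigma Additive Gaussian noise SD per channel
#'   (default 20).
#' @param bleedthrough_alpha Fraction of donor signal leaking into the
#'   acceptor channel, in [0, 0.3] (default 0: synthetic data are generated
#'   and corrected with the same coefficient).
#' @param background_donor,background_acceptor Constant channel offsets
#'   (default 0).
#' @param acceptor_bleach_hazard,simultaneous_bleach_hazard Per-frame
#'   probabilities of acceptor-only and simultaneous two-channel
#'   photobleaching (defaults 0.005 and 0.002).
#' @param pre_bleach_frames_min,post_bleach_frames_min Minimum number of
#'   frames before and after the bleach event (defaults 25 and 10).
#' @return An object of class `smfret_noise`.
#' @export
noise_spec <- function(total_intensity = 1000, channel_noise_sigma = 20,
                       bleedthrough_alpha = 0, background_donor = 0,
                       background_acceptor = 0,
                       acceptor_bleach_hazard = 0.005,
                       simultaneous_bleach_hazard = 0.002,
                       pre_bleach_frames_min = 25L,
                       post_bleach_frames_min = 10L) {
  check_scalar(total_intensity, "total_intensity", lower = 0)
  check_scalar(channel_noise_sigma, "channel_noise_sigma", lower = 0)
  check_scalar(bleedthrough_alpha, "bleedthrough_alpha", lower = 0, upper = 0.3)
  check_scalar(background_donor, "background_donor", lower = 0)
  check_scalar(background_acceptor, "background_acceptor", lower = 0)
  check_scalar(acceptor_bleach_hazard, "acceptor_bleach_hazard",
               lower = 0, upper = 1, closed_upper = FALSE)
  check_scalar(simultaneous_bleach_hazard, "simultaneous_bleach_hazard",
               lower = 0, upper = 1, closed_upper = FALSE)
  structure(
    list(total_intensity = total_intensity,
         channel_noise_sigma = channel_noise_sigma,
         bleedthrough_alpha = bleedthrough_alpha,
         background_donor = background_donor,
         background_acceptor = background_acceptor,
         acceptor_bleach_hazard = acceptor_bleach_hazard,
         simultaneous_bleach_hazard = simultaneous_bleach_hazard,
         pre_bleach_frames_min = check_count(pre_bleach_frames_min,
                                             "pre_bleach_frames_min"),
         post_bleach_frames_min = check_count(post_bleach_frames_min,
                                              "post_bleach_frames_min")),
    class = "smfret_noise")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param A Row-stochastic square matrix.
#' @return Probability vector `p` with `p %*% A = p`.
#' @export
stationary_dist <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) == 1L) return(1)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  p <- Re(e$vectors[, i])
  p <- p / sum(p)
  if (any(p < -1e-10)) stop_invalid("transition matrix has no valid stationary distribution")
  pmax(p, 0) / sum(pmax(p, 0))
}

# Reversible birth-death ("sequential") chain with a prescribed stationary
# distribution: Metropolis moves to adjacent states only, with neighbor
# proposal probability q. q <= 0.05 keeps every diagonal >= 0.9, i.e.
# seconds-scale dwells at a 0.1 s frame interval.
sequential_chain <- function(pi_target, q = 0.03) {
  k <- length(pi_target)
  check_simplex(pi_target, "stationary distribution", tol = 1e-8)
  A <- matrix(0, k, k)
  if (k == 1L) return(matrix(1, 1, 1))
  for (i in seq_len(k)) {
    if (i > 1L) A[i, i - 1L] <- q * min(1, pi_target[i - 1L] / pi_target[i])
    if (i < k) A[i, i + 1L] <- q * min(1, pi_target[i + 1L] / pi_target[i])
    A[i, i] <- 1 - sum(A[i, ])
  }
  A
}

# Preset stationary occupancies. Apo values are documented defaults (the
# source figures show, but do not print, absolute fractions); ligand
# presets shift them by the printed population deltas: CXCL12 raises CXCR4
# R* by 28 points and ACKR3 R*'+R* by 24 points.
preset_table <- function() {
  list(
    "apo-CXCR4" = list(
      means = c(0.85, 0.59, 0.19), occupancy = c(0.75, 0.20, 0.05)),
    "CXCL12-CXCR4" = list(
      means = c(0.85, 0.59, 0.19), occupancy = c(0.47, 0.20, 0.33)),
    "apo-ACKR3" = list(
      means = c(0.85, 0.66, 0.39, 0.11), occupancy = c(0.25, 0.25, 0.25, 0.25)),
    "CXCL12-ACKR3" = list(
      means = c(0.85, 0.66, 0.39, 0.11), occupancy = c(0.10, 0.16, 0.31, 0.43)),
    "VUF16840-ACKR3" = list(
      means = c(0.85, 0.66, 0.39, 0.11), occupancy = c(0.55, 0.25, 0.12, 0.08)),
    "Y257L-ACKR3" = list(
      means = c(0.85, 0.66, 0.39, 0.11), occupancy = c(0.65, 0.20, 0.08, 0.07)))
}

#' Named scenario presets for the study conditions
#'
#' Returns the registry of built-in scenarios. Each preset uses the reported
#' apparent-FRET state means for its receptor (CXCR4: 0.85/0.59/0.19;
#' ACKR3: 0.85/0.66/0.39/0.11, both ordered R, R', (R*'), R*), a shared
#' emission SD of 0.08, a 0.1 s frame interval, and a reversible
#' nearest-neighbor ("sequential") transition matrix whose stationary
#' distribution encodes the condition: apo-CXCR4 is inactive-dominant,
#' apo-ACKR3 near-uniform over its four states, CXCL12 presets shift
#' occupancy toward the active states by the reported deltas, VUF16840 and
#' the Y257L mutant shift toward the inactive state.
#'
#' @param names Optional character vector to subset the registry.
#' @return Named list of [scenario_spec()] objects.
#' @export
scenario_presets <- function(names = NULL) {
  tab <- preset_table()
  specs <- lapply(base::names(tab), function(nm) {
    p <- tab[[nm]]
    scenario_spec(nm, p$means, sequential_chain(p$occupancy))
  })
  base::names(specs) <- base::names(tab)
  if (!is.null(names)) {
    miss <- setdiff(names, base::names(specs))
    if (length(miss)) {
      stop_invalid("unknown scenario '%s'; available: %s", miss[1],
                   paste(base::names(specs), collapse = ", "))
    }
    specs <- specs[names]
  }
  specs
}

#' @rdname scenario_presets
#' @param name Single preset name.
#' @export
get_scenario <- function(name) {
  scenario_presets(name)[[1L]]
}
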