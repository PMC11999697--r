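#' Fractional state populations from idealized paths
#'
#' Frame-weighted occupancy of each state over all Viterbi paths of a
#' condition: `f_k` = frames labeled k / total frames.
#'
#' @param paths List of [viterbi()] paths.
#' @param K Number of states.
#' @param condition Optional condition label.
#' @return An object of class `smfret_populations`: `condition`, `fractions`
#'   (length K, summing to 1), `n_frames`, `n_traces`.
#' @export
state_populations <- function(paths, K, condition = NA_character_) {
  K <- check_count(K, "K", lower = 1L)
  if (!length(paths)) stop_data("state_populations needs at least one path")
  states <- unlist(lapply(paths, function(p) p$states), use.names = FALSE)
  if (!length(states)) stop_data("paths contain zero frames")
  if (any(states < 1L | states > K)) {
    stop_invalid("path labels exceed K = %d", K)
  }
  counts <- tabulate(states, nbins = K)
  structure(list(condition = condition, fractions = counts / sum(counts),
                 n_frames = sum(counts), n_traces = length(paths)),
            class = "smfret_populations")
}

#' @export
print.smfret_populations <- function(x, ...) {
  cat(sprintf("State populations%s (%d traces, %d frames):\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$n_traces, x$n_frames))
  cat(" ", paste(sprintf("%.3f", x$fractions), collapse = " "), "\n")
  invisible(x)
}

#' Per-state composite histograms and overall envelope
#'
#' Aggregates the apparent-FRET values Viterbi-assigned to each state into
#' one kernel density per state, scaled by the state's fractional
#' population so that the state curves sum pointwise to the overall
#' envelope (whose integral is 1). States with zero assigned frames yield a
#' zero curve and are flagged.
#'
#' @param trajectories List of [fret_trajectory()].
#' @param paths Aligned list of [viterbi()] paths.
#' @param K Number of states.
#' @param bandwidth Kernel SD in FRET units (default 0.04).
#' @return List with `state_curves` (list of `smfret_density`-like curves
#'   scaled by population), `envelope`, `fractions`, `empty_states`.
#' @export
per_state_histograms <- function(trajectories, paths, K, bandwidth = 0.04) {
  check_alignment(trajectories, paths)
  e_by_state <- split(
    unlist(lapply(trajectories, function(tr) tr$e_app), use.names = FALSE),
    factor(unlist(lapply(paths, function(p) p$states), use.names = FALSE),
           levels = seq_len(K)))
  n_total <- sum(lengths(e_by_state))
  fractions <- lengths(e_by_state) / n_total
  empty <- unname(which(lengths(e_by_state) == 0L))
  curves <- vector("list", K)
  envelope <- NULL
  for (k in seq_len(K)) {
    if (length(e_by_state[[k]])) {
      d <- kde_density(e_by_state[[k]], bandwidth)
      d$density <- d$density * fractions[k]
    } else {
      d <- kde_density(0.5, bandwidth) # grid template
      d$density <- d$density * 0
      d$n_points <- 0L
    }
    curves[[k]] <- d
    envelope <- if (is.null(envelope)) d$density else envelope + d$density
  }
  env <- curves[[1L]]
  env$density <- envelope
  env$n_points <- n_total
  list(state_curves = curves, envelope = env,
       fractions = as.numeric(fractions), empty_states = empty)
}

check_alignment <- function(trajectories, paths) {
  if (length(trajectories) != length(paths)) {
    stop_invalid("trajectories and paths must be aligned (lengths %d vs %d)",
                 length(trajectories), length(paths))
  }
  for (i in seq_along(paths)) {
    if (length(paths[[i]]$states) != trajectories[[i]]$n_frames) {
      stop_invalid("path %d length does not match its trajectory", i)
    }
  }
  invisible(TRUE)
}

#' Extract state-to-state transition events
#'
#' One event per consecutive label change in each idealized path. The event
#' coordinates `e_from`/`e_to` are the means of the raw apparent-FRET
#' values over the complete dwell before/after the change (not the fitted
#' state means), so distinct underlying FRET levels that share a model
#' state remain distinguishable in the transition density plot.
#'
#' @param trajectories List of [fret_trajectory()].
#' @param paths Aligned list of [viterbi()] paths.
#' @return A `data.frame` (class `smfret_transitions`) with columns
#'   `trace_id`, `from_state`, `to_state`, `e_from`, `e_to`, `dwell_before`
#'   (seconds).
#' @export
extract_transitions <- function(trajectories, paths) {
  check_alignment(trajectories, paths)
  rows <- list()
  for (i in seq_along(paths)) {
    st <- paths[[i]]$states
    e <- trajectories[[i]]$e_app
    dt <- trajectories[[i]]$frame_interval
    r <- rle(st)
    if (length(r$lengths) < 2L) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dwell_mean <- vapply(seq_along(starts), function(j) {
      mean(e[starts[j]:ends[j]])
    }, numeric(1))
    j <- seq_len(length(r$lengths) - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      trace_id = paths[[i]]$trace_id,
      from_state = r$values[j], to_state = r$values[j + 1L],
      e_from = dwell_mean[j], e_to = dwell_mean[j + 1L],
      dwell_before = r$lengths[j] * dt, stringsAsFactors = FALSE)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(trace_id = character(), from_state = integer(),
               to_state = integer(), e_from = numeric(), e_to = numeric(),
               dwell_before = numeric(), stringsAsFactors = FALSE)
  }
  class(ev) <- c("smfret_transitions", "data.frame")
  ev
}

#' Transition density probability grid
#'
#' 2-D Gaussian kernel density of (initial FRET, final FRET) event
#' coordinates, normalized so the cell-area-weighted sum is 1. Off-diagonal
#' peaks reveal which states interconvert. Peaks are local maxima (8-cell
#' neighborhood) above `peak_frac` of the global maximum.
#'
#' @param events An `smfret_transitions` data frame (see
#'   [extract_transitions()]).
#' @param smoothing_sigma Kernel SD in FRET units (default 0.03).
#' @param grid_limits,grid_n Square grid (defaults [-0.2, 1.2], 128).
#' @param peak_frac Peak detection threshold as a fraction of the global
#'   maximum (default 0.1).
#' @return An object of class `smfret_tdp`: `x`, `y`, `density`,
#'   `n_transitions`, `smoothing_sigma`, `peaks` (data.frame `x`, `y`,
#'   `value`), `empty` flag.
#' @export
build_tdp <- function(events, smoothing_sigma = 0.03,
                      grid_limits = c(-0.2, 1.2), grid_n = 128L,
                      peak_frac = 0.1) {
  check_scalar(smoothing_sigma, "smoothing_sigma", lower = 0, closed_lower = FALSE)
  g <- seq(grid_limits[1L], grid_limits[2L], length.out = grid_n)
  cell <- (g[2L] - g[1L])^2
  n_ev <- nrow(events)
  if (n_ev == 0L) {
    return(structure(list(x = g, y = g, density = matrix(0, grid_n, grid_n),
                          n_transitions = 0L, smoothing_sigma = smoothing_sigma,
                          peaks = data.frame(x = numeric(), y = numeric(),
                                             value = numeric()),
                          empty = TRUE),
                     class = "smfret_tdp"))
  }
  # separable kernel: density = Dx %*% t(Dy) over events
  dx <- vapply(events$e_from, function(m) dnorm(g, m, smoothing_sigma),
               numeric(grid_n))
  dy <- vapply(events$e_to, function(m) dnorm(g, m, smoothing_sigma),
               numeric(grid_n))
  dens <- dx %*% t(dy) # x indexes rows, y indexes columns
  dens <- dens / (sum(dens) * cell)
  peaks <- find_grid_peaks(g, g, dens, peak_frac)
  structure(list(x = g, y = g, density = dens, n_transitions = n_ev,
                 smoothing_sigma = smoothing_sigma, peaks = peaks,
                 empty = FALSE),
            class = "smfret_tdp")
}

find_grid_peaks <- function(gx, gy, dens, peak_frac) {
  nr <- nrow(dens)
  nc <- ncol(dens)
  thr <- peak_frac * max(dens)
  hits <- list()
  for (i in 2:(nr - 1L)) {
    for (j in 2:(nc - 1L)) {
      v <- dens[i, j]
      if (v < thr) next
      nb <- dens[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
      if (v >= max(nb)) {
        hits[[length(hits) + 1L]] <- data.frame(x = gx[i], y = gy[j], value = v)
      }
    }
  }
  if (!length(hits)) return(data.frame(x = numeric(), y = numeric(), value = numeric()))
  out <- do.call(rbind, hits)
  out[order(-out$value), , drop = FALSE]
}

#' @export
print.smfret_tdp <- function(x, ...) {
  cat(sprintf("TDP grid: %d transitions, sigma = %.3f, %d peak(s)\n",
              x$n_transitions, x$smoothing_sigma, nrow(x$peaks)))
  invisible(x)
}

#' Unordered cross-peak pairs of a transition density plot
#'
#' Groups off-diagonal TDP peaks into unordered pairs: a forward peak at
#' (a, b) and its mirror at (b, a) count as one pair. Used to test
#' connectivity arguments -- a mixed-labeling artifact with two
#' non-interconverting FRET level pairs yields four levels but only two
#' cross-peak pairs.
#'
#' @param tdp An `smfret_tdp`.
#' @param diag_tol Minimum |x - y| for a peak to count as off-diagonal
#'   (default 0.1).
#' @param match_tol Coordinate tolerance for pairing mirrored peaks
#'   (default 0.06).
#' @return A `data.frame` with one row per unordered pair: `low`, `high`
#'   (the two FRET levels), `n_peaks` (1 if only one direction was
#'   detected, 2 if both).
#' @export
tdp_cross_peak_pairs <- function(tdp, diag_tol = 0.1, match_tol = 0.06) {
  pk <- tdp$peaks
  pk <- pk[abs(pk$x - pk$y) > diag_tol, , drop = FALSE]
  if (!nrow(pk)) {
    return(data.frame(low = numeric(), high = numeric(), n_peaks = integer()))
  }
  lo <- pmin(pk$x, pk$y)
  hi <- pmax(pk$x, pk$y)
  used <- rep(FALSE, nrow(pk))
  out <- list()
  for (i in seq_len(nrow(pk))) {
    if (used[i]) next
    grp <- which(!used & abs(lo - lo[i]) <= match_tol & abs(hi - hi[i]) <= match_tol)
    used[grp] <- TRUE
    out[[length(out) + 1L]] <- data.frame(low = mean(lo[grp]), high = mean(hi[grp]),
                                          n_peaks = length(grp))
  }
  do.call(rbind, out)
}

#' Dwell-time table from idealized paths
#'
#' Collects completed dwells per state: the first and last dwell of every
#' trace are censored (their true duration is unknown), every interior run
#' of length L contributes a dwell of `L * frame_interval` seconds.
#' Exponential rates are estimated as 1/mean.
#'
#' @param paths List of [viterbi()] paths.
#' @param K Number of states.
#' @param frame_interval Frame interval in seconds.
#' @param condition Optional label.
#' @return An object of class `smfret_dwells`: `samples` (list of dwell
#'   vectors per state), `summary` (data.frame with `state`, `count`,
#'   `mean_s`, `rate_per_s`), `empty_states`, `condition`.
#' @export
dwell_times <- function(paths, K, frame_interval = 0.1,
                        condition = NA_character_) {
  K <- check_count(K, "K", lower = 1L)
  samples <- vector("list", K)
  for (p in paths) {
    r <- rle(p$states)
    nr <- length(r$lengths)
    if (nr < 3L) next # no interior (completed) dwell
    for (j in 2:(nr - 1L)) {
      s <- r$values[j]
      samples[[s]] <- c(samples[[s]], r$lengths[j] * frame_interval)
    }
  }
  counts <- lengths(samples)
  means <- vapply(samples, function(s) if (length(s)) mean(s) else NA_real_,
                  numeric(1))
  summary <- data.frame(state = seq_len(K), count = counts, mean_s = means,
                        rate_per_s = 1 / means)
  structure(list(samples = samples, summary = summary,
                 empty_states = which(counts == 0L), condition = condition),
            class = "smfret_dwells")
}

#' @export
print.smfret_dwells <- function(x, ...) {
  cat("Completed dwell times by state:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Population shift between two conditions
#'
#' Per-state differences `(f_b - f_a) * 100` in percentage points, plus
#' optional grouped deltas (e.g. active + active-like states combined).
#'
#' @param pop_a,pop_b [state_populations()] for the two conditions (same K
#'   and state labeling: state 1 = highest FRET).
#' @param groups Optional named list of state-index vectors, e.g.
#'   `list(active = c(3, 4))`.
#' @return An object of class `smfret_comparison`: `condition_a`,
#'   `condition_b`, `delta_fractions` (percentage points, summing to 0),
#'   `group_deltas`.
#' @export
compare_conditions <- function(pop_a, pop_b, groups = NULL) {
  stopifnot(inherits(pop_a, "smfret_populations"),
            inherits(pop_b, "smfret_populations"))
  if (length(pop_a$fractions) != length(pop_b$fractions)) {
    stop_invalid("conditions have different state counts (%d vs %d)",
                 length(pop_a$fractions), length(pop_b$fractions))
  }
  delta <- (pop_b$fractions - pop_a$fractions) * 100
  group_deltas <- NULL
  if (!is.null(groups)) {
    group_deltas <- vapply(groups, function(idx) sum(delta[idx]), numeric(1))
  }
  structure(list(condition_a = pop_a$condition, condition_b = pop_b$condition,
                 delta_fractions = delta, group_deltas = group_deltas),
            class = "smfret_comparison")
}

#' @export
print.smfret_comparison <- function(x, ...) {
  cat(sprintf("Population shift %s -> %s (percentage points):\n",
              x$condition_a, x$condition_b))
  cat(" ", paste(sprintf("%+.1f", x$delta_fractions), collapse = " "), "\n")
  if (!is.null(x$group_deltas)) {
    for (g in names(x$group_deltas)) {
      cat(sprintf("  %s: %+.1f\n", g, x$group_deltas[[g]]))
    }
  }
  invisible(x)
}
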