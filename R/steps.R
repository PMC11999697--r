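#' Detection and screening thresholds
#'
#' All tunables of the automated replacement for manual trace screening.
#' The documented keys (usable from a JSON config file through
#' [run_config()]) are:
#' \describe{
#'   \item{step_threshold}{Minimum two-sample t statistic for a change point
#'     to count as a step (default 4).}
#'   \item{min_segment}{Minimum frames on either side of a split (default 5).}
#'   \item{simultaneity_window}{Maximum frame offset for acceptor and
#'     total-intensity steps to count as one simultaneous event (default 1).}
#'   \item{acceptor_low_frac}{A post-step acceptor segment must stay below
#'     this fraction of the total intensity to qualify as bleached
#'     (default 0.06).}
#'   \item{donor_high_frac}{After an acceptor-only bleach the donor must
#'     carry at least this fraction of the total intensity (default 0.85).}
#'   \item{total_low_frac}{After a simultaneous bleach the summed intensity
#'     must fall below this fraction (default 0.25).}
#'   \item{quiet_sd_frac}{A bleached segment must be quiet: SD below this
#'     fraction of the total intensity (default 0.045). Pre-bleach segments
#'     carry the conformational FRET jitter and are never this quiet.}
#'   \item{anticorrelation_max}{Maximum pre-bleach donor/acceptor Pearson
#'     correlation for acceptance (default -0.2).}
#'   \item{min_pre_frames}{Minimum pre-bleach length (default 20).}
#' }
#'
#' @param step_threshold,min_segment,simultaneity_window,acceptor_low_frac,donor_high_frac,total_low_frac,quiet_sd_frac,anticorrelation_max,min_pre_frames See above.
#' @return An object of class `smfret_screen_config`.
#' @export
screen_config <- function(step_threshold = 4, min_segment = 5L,
                          simultaneity_window = 1L, acceptor_low_frac = 0.06,
                          donor_high_frac = 0.85, total_low_frac = 0.25,
                          quiet_sd_frac = 0.045, anticorrelation_max = -0.2,
                          min_pre_frames = 20L) {
  structure(list(step_threshold = check_scalar(step_threshold, "step_threshold", lower = 0),
                 min_segment = check_count(min_segment, "min_segment", lower = 2L),
                 simultaneity_window = check_count(simultaneity_window, "simultaneity_window"),
                 acceptor_low_frac = acceptor_low_frac,
                 donor_high_frac = donor_high_frac,
                 total_low_frac = total_low_frac,
                 quiet_sd_frac = quiet_sd_frac,
                 anticorrelation_max = anticorrelation_max,
                 min_pre_frames = check_count(min_pre_frames, "min_pre_frames", lower = 2L)),
            class = "smfret_screen_config")
}

# Best single split of x[lo:hi] by least squares (the exhaustive
# change-point criterion): returns the split index (first frame of the
# right segment, absolute), the mean difference, and the two-sample t
# statistic. O(n) via cumulative sums.
best_split <- function(x, lo, hi, min_segment) {
  n <- hi - lo + 1L
  if (n < 2L * min_segment) return(NULL)
  seg <- x[lo:hi]
  cs <- cumsum(seg)
  cs2 <- cumsum(seg^2)
  n1 <- min_segment:(n - min_segment)
  n2 <- n - n1
  s1 <- cs[n1]
  s2 <- cs[n] - s1
  m1 <- s1 / n1
  m2 <- s2 / n2
  sse <- (cs2[n] - (cs2[n1])) - s2^2 / n2 + (cs2[n1] - s1^2 / n1)
  # maximize the t statistic (equivalently minimize total within-SSE)
  pooled <- sqrt(pmax(sse, 0) / pmax(n - 2L, 1L))
  tstat <- abs(m2 - m1) / pmax(pooled * sqrt(1 / n1 + 1 / n2), 1e-12)
  i <- which.max(tstat)
  list(frame = lo + n1[i], delta = m2[i] - m1[i], score = tstat[i])
}

#' Detect intensity steps by binary segmentation
#'
#' Recursively splits the series at the least-squares change point and keeps
#' splits whose two-sample t statistic reaches `threshold`. Traces are short
#' enough that every candidate split frame is scanned exhaustively.
#'
#' @param x Numeric series.
#' @param min_segment Minimum frames on either side of any split.
#' @param threshold Minimum t statistic for a step.
#' @return `data.frame` with columns `frame` (first frame of the new level),
#'   `delta` (level change), `score`, ordered by frame. Zero rows if no step
#'   qualifies.
#' @export
find_steps <- function(x, min_segment = 5L, threshold = 4) {
  out <- list()
  recurse <- function(lo, hi) {
    sp <- best_split(x, lo, hi, min_segment)
    if (is.null(sp) || sp$score < threshold) return(invisible())
    out[[length(out) + 1L]] <<- sp
    recurse(lo, sp$frame - 1L)
    recurse(sp$frame, hi)
  }
  recurse(1L, length(x))
  if (!length(out)) {
    return(data.frame(frame = integer(), delta = numeric(), score = numeric()))
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  df[order(df$frame), , drop = FALSE]
}

segment_stats <- function(x, starts, ends) {
  vapply(seq_along(starts), function(i) {
    seg <- x[starts[i]:ends[i]]
    c(mean(seg), if (length(seg) > 1L) sd(seg) else 0)
  }, numeric(2))
}

#' Locate and classify the photobleach event of a trace
#'
#' Change points are searched independently in the acceptor channel and in
#' the summed two-channel intensity. A detected acceptor down-step is a
#' bleach candidate only if, up to the next change point, the acceptor
#' stays near background, the donor carries essentially the whole photon
#' budget (FRET is gone), and the segment is quiet (no conformational
#' jitter); a total-intensity down-step to near background is a simultaneous
#' candidate. Candidates within `simultaneity_window` frames of each other
#' merge into one simultaneous event. The reported bleach frame is the
#' earliest event; FRET state transitions, which move the acceptor but
#' conserve the summed intensity and leave the acceptor well above
#' background, are never classified as bleaching.
#'
#' @param trace An [intensity_trace()] (corrected or raw; with substantial
#'   donor bleed-through, correct first).
#' @param config A [screen_config()].
#' @return List with `bleach_frame` (first post-bleach frame or `NA`),
#'   `bleach_class`, `n_steps_acceptor`/`n_steps_total` (raw downward step
#'   counts), `n_bleach_events`, and `events` (data.frame of bleach-class
#'   events).
#' @export
detect_photobleach <- function(trace, config = screen_config()) {
  stopifnot(inherits(trace, "smfret_trace"))
  donor <- trace$donor
  acceptor <- trace$acceptor
  total <- donor + acceptor
  n <- length(total)
  if (n < 2L * config$min_segment) {
    stop_data("trace '%s' too short for step detection (%d frames)",
              trace$trace_id, n)
  }
  i_est <- as.numeric(quantile(total, 0.95, names = FALSE))
  steps_acc <- find_steps(acceptor, config$min_segment, config$step_threshold)
  steps_tot <- find_steps(total, config$min_segment, config$step_threshold)
  boundaries <- sort(unique(c(steps_acc$frame, steps_tot$frame, n + 1L)))

  events <- list()
  down_acc <- steps_acc[steps_acc$delta < 0, , drop = FALSE]
  for (f in down_acc$frame) {
    seg_end <- min(boundaries[boundaries > f]) - 1L
    m_acc <- mean(acceptor[f:seg_end])
    m_don <- mean(donor[f:seg_end])
    s_acc <- if (seg_end > f) sd(acceptor[f:seg_end]) else 0
    if (m_acc <= config$acceptor_low_frac * i_est &&
        m_don >= config$donor_high_frac * i_est &&
        s_acc <= config$quiet_sd_frac * i_est) {
      events[[length(events) + 1L]] <- data.frame(frame = f, class = "acceptor_only")
    }
  }
  down_tot <- steps_tot[steps_tot$delta < 0, , drop = FALSE]
  for (f in down_tot$frame) {
    seg_end <- min(boundaries[boundaries > f]) - 1L
    m_tot <- mean(total[f:seg_end])
    s_tot <- if (seg_end > f) sd(total[f:seg_end]) else 0
    if (m_tot <= config$total_low_frac * i_est &&
        s_tot <= config$quiet_sd_frac * i_est) {
      events[[length(events) + 1L]] <- data.frame(frame = f, class = "simultaneous")
    }
  }

  if (length(events)) {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev$frame), , drop = FALSE]
    # merge acceptor/total events within the simultaneity window
    keep <- rep(TRUE, nrow(ev))
    for (i in seq_len(nrow(ev))) {
      if (!keep[i]) next
      close <- which(keep & abs(ev$frame - ev$frame[i]) <= config$simultaneity_window)
      if (length(close) > 1L) {
        if (length(unique(ev$class[close])) > 1L) ev$class[min(close)] <- "simultaneous"
        ev$frame[min(close)] <- min(ev$frame[close])
        keep[setdiff(close, min(close))] <- FALSE
      }
    }
    ev <- ev[keep, , drop = FALSE]
  } else {
    ev <- data.frame(frame = integer(), class = character())
  }

  list(bleach_frame = if (nrow(ev)) ev$frame[1L] else NA_integer_,
       bleach_class = if (nrow(ev)) ev$class[1L] else "none",
       n_steps_acceptor = nrow(down_acc),
       n_steps_total = nrow(down_tot),
       n_bleach_events = nrow(ev),
       events = ev)
}

#' Screen a trace for single-molecule behavior
#'
#' Automated version of the manual screen applied to real recordings: a
#' trace is accepted if it shows exactly one photobleach event (acceptor
#' only or simultaneous), its pre-bleach donor and acceptor are
#' anti-correlated, and the pre-bleach segment is long enough to contribute
#' to the global fit. Every failed rule is listed in `reasons`
#' (`"no_bleach"`, `"multi_step"`, `"not_anticorrelated"`, `"no_dynamics"`,
#' `"too_short"`); `accepted` is `TRUE` iff `reasons` is empty.
#'
#' @param trace An [intensity_trace()].
#' @param config A [screen_config()].
#' @param detection Optional result of [detect_photobleach()] on the same
#'   trace; computed if missing.
#' @return An object of class `smfret_screen`: list with `trace_id`,
#'   `accepted`, `reasons`, `anticorrelation`, `bleach_frame`,
#'   `bleach_class`, `n_detected_steps_acceptor`, `n_detected_steps_total`.
#' @export
screen_trace <- function(trace, config = screen_config(), detection = NULL) {
  stopifnot(inherits(trace, "smfret_trace"))
  if (is.null(detection)) detection <- detect_photobleach(trace, config)
  reasons <- character()
  if (detection$n_bleach_events == 0L) {
    reasons <- c(reasons, "no_bleach")
  } else if (detection$n_bleach_events > 1L) {
    reasons <- c(reasons, "multi_step")
  }
  pre_end <- if (!is.na(detection$bleach_frame)) detection$bleach_frame - 1L
             else length(trace$donor)
  if (pre_end < config$min_pre_frames) reasons <- c(reasons, "too_short")
  anticorr <- NA_real_
  if (pre_end >= 3L) {
    d <- trace$donor[1:pre_end]
    a <- trace$acceptor[1:pre_end]
    if (sd(d) < 1e-12 || sd(a) < 1e-12) {
      reasons <- c(reasons, "no_dynamics")
    } else {
      anticorr <- cor(d, a)
      if (anticorr > config$anticorrelation_max) {
        reasons <- c(reasons, "not_anticorrelated")
      }
    }
  } else if (pre_end >= 1L) {
    reasons <- c(reasons, "no_dynamics")
  }
  structure(list(trace_id = trace$trace_id, accepted = length(reasons) == 0L,
                 reasons = reasons, anticorrelation = anticorr,
                 bleach_frame = detection$bleach_frame,
                 bleach_class = detection$bleach_class,
                 n_detected_steps_acceptor = detection$n_steps_acceptor,
                 n_detected_steps_total = detection$n_steps_total),
            class = "smfret_screen")
}

#' Screen a collection of traces and keep the accepted FRET trajectories
#'
#' Convenience wrapper: corrects each trace (unless already corrected),
#' detects its photobleach, screens it, and computes the pre-bleach
#' apparent-FRET trajectory of every accepted molecule.
#'
#' @param traces List of [intensity_trace()].
#' @param config A [screen_config()].
#' @param correction A [correction_params()] applied to uncorrected traces.
#' @return List with `trajectories` (accepted [fret_trajectory()]s),
#'   `reports` (all [screen_trace()] reports), `traces` (annotated corrected
#'   traces), and `acceptance_rate`.
#' @export
screen_experiment <- function(traces, config = screen_config(),
                              correction = correction_params()) {
  if (inherits(traces, "smfret_experiment")) traces <- traces$traces
  reports <- vector("list", length(traces))
  trajectories <- list()
  annotated <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (!tr$corrected) tr <- correct_intensities(tr, correction)
    det <- detect_photobleach(tr, config)
    rep <- screen_trace(tr, config, det)
    tr$bleach_frame <- det$bleach_frame
    tr$bleach_class <- det$bleach_class
    annotated[[i]] <- tr
    reports[[i]] <- rep
    if (rep$accepted) {
      trajectories[[length(trajectories) + 1L]] <- compute_fret(tr)
    }
  }
  list(trajectories = trajectories, reports = reports, traces = annotated,
       acceptance_rate = if (length(traces)) {
         mean(vapply(reports, `[[`, logical(1), "accepted"))
       } else {
         NA_real_
       })
}
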