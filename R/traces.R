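#' Two-channel intensity trace for a single molecule
#'
#' Holds the per-frame donor and acceptor intensity series of one molecule,
#' the camera frame interval, and (once determined) the photobleach
#' annotation. Frames are 1-indexed in R; `bleach_frame` is the index of the
#' first post-bleach frame, so the usable pre-bleach segment is
#' `1:(bleach_frame - 1)`.
#'
#' @param trace_id Single string identifying the molecule.
#' @param donor,acceptor Numeric vectors of equal length (>= 2) of per-frame
#'   intensities in arbitrary units.
#' @param frame_interval Frame interval in seconds (default 0.1).
#' @param bleach_frame Integer index of the first post-bleach frame in
#'   `[2, length]`, or `NA` if no bleach has been identified.
#' @param bleach_class One of `"none"`, `"acceptor_only"`, `"simultaneous"`.
#' @param corrected Logical; whether bleed-through/background correction has
#'   been applied.
#' @return An object of class `smfret_trace`.
#' @export
intensity_trace <- function(trace_id, donor, acceptor, frame_interval = 0.1,
                            bleach_frame = NA_integer_,
                            bleach_class = c("none", "acceptor_only",
                                             "simultaneous"),
                            corrected = FALSE) {
  bleach_class <- match.arg(bleach_class)
  if (!is.character(trace_id) || length(trace_id) != 1L) {
    stop_invalid("trace_id must be a single string")
  }
  n <- length(donor)
  if (n < 2L || length(acceptor) != n) {
    stop_invalid("donor and acceptor must have equal length >= 2 (trace '%s')",
                 trace_id)
  }
  if (any(!is.finite(donor)) || any(!is.finite(acceptor))) {
    stop_invalid("intensities must be finite (trace '%s')", trace_id)
  }
  check_scalar(frame_interval, "frame_interval", lower = 0, closed_lower = FALSE)
  if (!is.na(bleach_frame)) {
    bleach_frame <- check_count(bleach_frame, "bleach_frame", lower = 2L)
    if (bleach_frame > n) {
      stop_invalid("bleach_frame must be within [2, %d] (trace '%s')", n, trace_id)
    }
  }
  structure(
    list(trace_id = trace_id, donor = as.numeric(donor),
         acceptor = as.numeric(acceptor), frame_interval = frame_interval,
         bleach_frame = if (is.na(bleach_frame)) NA_integer_ else bleach_frame,
         bleach_class = bleach_class, corrected = isTRUE(corrected)),
    class = "smfret_trace")
}

#' @export
print.smfret_trace <- function(x, ...) {
  cat(sprintf("smFRET trace '%s': %d frames @ %.3g s, %s, bleach %s (%s)\n",
              x$trace_id, length(x$donor), x$frame_interval,
              if (x$corrected) "corrected" else "raw",
              if (is.na(x$bleach_frame)) "none" else x$bleach_frame,
              x$bleach_class))
  invisible(x)
}

n_frames <- function(trace) length(trace$donor)

prebleach_idx <- function(trace) {
  if (is.na(trace$bleach_frame)) seq_len(n_frames(trace))
  else seq_len(trace$bleach_frame - 1L)
}

#' Bleed-through and background correction parameters
#'
#' @param bleedthrough_alpha Fraction of donor signal leaking into the
#'   acceptor channel, in [0, 0.3].
#' @param background_donor,background_acceptor Constant channel offsets.
#' @return An object of class `smfret_correction`.
#' @export
correction_params <- function(bleedthrough_alpha = 0, background_donor = 0,
                              background_acceptor = 0) {
  check_scalar(bleedthrough_alpha, "bleedthrough_alpha", lower = 0, upper = 0.3)
  check_scalar(background_donor, "background_donor")
  check_scalar(background_acceptor, "background_acceptor")
  structure(list(bleedthrough_alpha = bleedthrough_alpha,
                 background_donor = background_donor,
                 background_acceptor = background_acceptor),
            class = "smfret_correction")
}

#' Correct a trace for background and donor bleed-through
#'
#' Applies `donor' = donor - background_donor` and
#' `acceptor' = acceptor - background_acceptor - alpha * donor'`. Negative
#' corrected intensities are permitted (no flooring), preserving the noise
#' structure assumed by the Gaussian emission model downstream. Applying the
#' correction twice is an error.
#'
#' @param trace An [intensity_trace()].
#' @param params A [correction_params()].
#' @return The corrected trace (with `corrected = TRUE`).
#' @export
correct_intensities <- function(trace, params = correction_params()) {
  stopifnot(inherits(trace, "smfret_trace"))
  stopifnot(inherits(params, "smfret_correction"))
  if (trace$corrected) {
    stop_invalid("trace '%s' is already corrected", trace$trace_id)
  }
  donor <- trace$donor - params$background_donor
  acceptor <- trace$acceptor - params$background_acceptor -
    params$bleedthrough_alpha * donor
  out <- trace
  out$donor <- donor
  out$acceptor <- acceptor
  out$corrected <- TRUE
  out
}

#' Apparent FRET efficiency trajectory
#'
#' @param trace_id Single string.
#' @param e_app Numeric vector of per-frame apparent FRET efficiencies
#'   (finite; values outside [0, 1] are allowed and not clamped).
#' @param frame_interval Frame interval in seconds.
#' @param n_dropped Number of frames dropped for a degenerate denominator.
#' @return An object of class `smfret_fret`.
#' @export
fret_trajectory <- function(trace_id, e_app, frame_interval = 0.1,
                            n_dropped = 0L) {
  if (any(!is.finite(e_app))) stop_invalid("e_app must be finite")
  if (length(e_app) < 1L) stop_data("empty FRET trajectory ('%s')", trace_id)
  structure(list(trace_id = trace_id, e_app = as.numeric(e_app),
                 frame_interval = frame_interval,
                 n_frames = length(e_app),
                 n_dropped = as.integer(n_dropped)),
            class = "smfret_fret")
}

#' Compute the apparent FRET efficiency trajectory of a trace
#'
#' `E_app[t] = I_A[t] / (I_A[t] + I_D[t])` over the pre-bleach segment of a
#' corrected trace (the full trace if no bleach is annotated). Frames whose
#' total intensity falls at or below `denominator_floor` are dropped and
#' counted in `n_dropped`; values are not clamped to [0, 1].
#'
#' @param trace A corrected [intensity_trace()] with bleach annotation
#'   already determined (see [detect_photobleach()]).
#' @param denominator_floor Minimum total intensity for a frame to be used
#'   (default 1e-9).
#' @return A [fret_trajectory()].
#' @export
compute_fret <- function(trace, denominator_floor = 1e-9) {
  stopifnot(inherits(trace, "smfret_trace"))
  if (!trace$corrected) {
    stop_invalid("trace '%s' must be corrected before computing FRET (run correct_intensities)",
                 trace$trace_id)
  }
  idx <- prebleach_idx(trace)
  d <- trace$donor[idx]
  a <- trace$acceptor[idx]
  tot <- a + d
  keep <- tot > denominator_floor
  if (!any(keep)) {
    stop_data("all %d pre-bleach frames of trace '%s' are degenerate",
              length(idx), trace$trace_id)
  }
  fret_trajectory(trace$trace_id, a[keep] / tot[keep], trace$frame_interval,
                  n_dropped = sum(!keep))
}
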