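# Trace exchange format ("SMT-TSV"): a UTF-8 tab-separated data file with
# header trace_id/frame_index/donor/acceptor, rows sorted by
# (trace_id, frame_index) with frame_index contiguous from 0 per trace,
# plus a JSON manifest `<basename>.manifest.json` holding format_version,
# frame_interval_s, channel_units, correction_state and per-trace metadata.
# Intensities are written with 17 significant digits so a round trip is
# value-exact.

FORMAT_VERSION <- "1.0"

manifest_path <- function(path) sub("\\.tsv$", "", path) |> paste0(".manifest.json")

#' Write a trace collection in the SMT-TSV exchange format
#'
#' @param traces List of [intensity_trace()] (possibly empty).
#' @param path Output `.tsv` path; the JSON manifest is written next to it
#'   as `<basename>.manifest.json`.
#' @param extra Optional named list merged into the manifest (e.g. a config
#'   hash).
#' @return Invisibly, the manifest path.
#' @export
write_traces <- function(traces, path, extra = NULL) {
  if (inherits(traces, "smfret_experiment")) traces <- traces$traces
  ids <- vapply(traces, function(tr) tr$trace_id, character(1))
  ord <- order(ids, method = "radix")
  traces <- traces[ord]
  con <- file(path, open = "wb")
  writeLines("trace_id\tframe_index\tdonor\tacceptor", con)
  for (tr in traces) {
    n <- length(tr$donor)
    writeLines(sprintf("%s\t%d\t%.17g\t%.17g", tr$trace_id, 0:(n - 1L),
                       tr$donor, tr$acceptor), con)
  }
  close(con)
  intervals <- unique(vapply(traces, function(tr) tr$frame_interval, numeric(1)))
  if (length(intervals) > 1L) {
    stop_invalid("all traces in one file must share a frame interval")
  }
  states <- unique(vapply(traces, function(tr) tr$corrected, logical(1)))
  manifest <- list(
    format_version = FORMAT_VERSION,
    frame_interval_s = if (length(intervals)) intervals else 0.1,
    channel_units = "arbitrary",
    correction_state = if (length(states) && all(states)) "corrected" else "raw",
    traces = lapply(traces, function(tr) {
      rec <- list(trace_id = tr$trace_id, n_frames = length(tr$donor),
                  bleach_class = tr$bleach_class)
      if (!is.na(tr$bleach_frame)) rec$bleach_frame <- tr$bleach_frame - 1L
      rec
    }))
  if (!is.null(extra)) manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path(path))
}

#' Read a trace collection from the SMT-TSV exchange format
#'
#' @param path Path to the `.tsv` data file; the manifest
#'   `<basename>.manifest.json` must exist next to it.
#' @return List of [intensity_trace()], ordered by trace_id.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop_parse("trace file '%s' does not exist", path)
  mpath <- manifest_path(path)
  if (!file.exists(mpath)) {
    stop_parse("manifest '%s' missing for trace file '%s'", mpath, path)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("trace_id", "frame_index", "donor", "acceptor")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_parse("file '%s': missing column(s) %s [rule: required-columns]",
               path, paste(missing, collapse = ", "))
  }
  if (!nrow(df)) return(list())
  meta <- list()
  for (m in manifest$traces) meta[[m$trace_id]] <- m
  fi <- manifest$frame_interval_s
  corrected <- identical(manifest$correction_state, "corrected")
  out <- list()
  for (id in unique(df$trace_id)) {
    sub <- df[df$trace_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame_index), , drop = FALSE]
    if (anyDuplicated(sub$frame_index)) {
      stop_parse("file '%s', trace '%s': duplicate frame_index [rule: unique-frames]",
                 path, id)
    }
    if (!identical(as.integer(sub$frame_index), 0:(nrow(sub) - 1L))) {
      stop_parse("file '%s', trace '%s': frame_index must be contiguous from 0 [rule: contiguous-frames]",
                 path, id)
    }
    m <- meta[[id]]
    bf <- if (length(m$bleach_frame)) as.integer(m$bleach_frame) + 1L else NA_integer_
    bc <- if (!is.null(m$bleach_class)) m$bleach_class else "none"
    out[[id]] <- intensity_trace(id, sub$donor, sub$acceptor,
                                 frame_interval = fi, bleach_frame = bf,
                                 bleach_class = bc, corrected = corrected)
  }
  out[order(names(out), method = "radix")]
}

rle_encode <- function(states) {
  r <- rle(as.integer(states))
  paste(sprintf("%dx%d", r$values, r$lengths), collapse = ",")
}

rle_decode <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(-?[0-9]+)x([0-9]+)$", parts))
  if (any(lengths(m) != 3L)) stop_parse("malformed run-length encoding '%s'", s)
  vals <- as.integer(vapply(m, `[`, character(1), 2L))
  lens <- as.integer(vapply(m, `[`, character(1), 3L))
  rep(vals, lens)
}

#' Write/read a ground-truth sidecar
#'
#' One TSV record per trace: `trace_id`, `bleach_frame` (0-based first
#' post-bleach frame, or empty), `bleach_class`, and the run-length-encoded
#' state path (`"1x12,2x5,..."`, 1-based labels).
#'
#' @param truth List of ground-truth records from [simulate_experiment()].
#' @param path Output `.tsv` path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, open = "wb")
  writeLines("trace_id\tbleach_frame\tbleach_class\tstate_path_rle", con)
  ids <- vapply(truth, function(x) x$trace_id, character(1))
  for (x in truth[order(ids, method = "radix")]) {
    writeLines(sprintf("%s\t%s\t%s\t%s", x$trace_id,
                       if (is.na(x$bleach_frame)) "" else x$bleach_frame - 1L,
                       x$bleach_class, rle_encode(x$state_path)), con)
  }
  close(con)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character", "character"))
  lapply(seq_len(nrow(df)), function(i) {
    list(trace_id = df$trace_id[i],
         bleach_frame = if (nzchar(df$bleach_frame[i])) {
           as.integer(df$bleach_frame[i]) + 1L
         } else {
           NA_integer_
         },
         bleach_class = df$bleach_class[i],
         state_path = rle_decode(df$state_path_rle[i]))
  })
}

#' Serialize / deserialize a fitted HMM as JSON
#'
#' @param model An [hmm_model()] (or an `smfret_fit`, whose model is
#'   written along with fit metadata).
#' @param path Output `.json` path.
#' @param extra Optional named list merged into the JSON (e.g. config
#'   hash, seed).
#' @return Invisibly, `path` (write) / the model (read).
#' @export
write_model <- function(model, path, extra = NULL) {
  fit_meta <- NULL
  if (inherits(model, "smfret_fit")) {
    fit_meta <- list(n_iterations = model$n_iterations,
                     converged = model$converged,
                     n_trajectories = model$n_trajectories,
                     n_frames = model$n_frames,
                     loglik = max(model$loglik_trajectory),
                     occupancy = model$occupancy)
    model <- model$model
  }
  obj <- list(format_version = FORMAT_VERSION, n_states = model$n_states,
              means = model$means, shared_variance = model$shared_variance,
              transition_matrix = apply(model$transition_matrix, 1L, identity,
                                        simplify = FALSE),
              initial_dist = model$initial_dist, fit = fit_meta)
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_model(obj$means, obj$shared_variance,
            do.call(rbind, if (is.list(obj$transition_matrix)) {
              obj$transition_matrix
            } else {
              list(obj$transition_matrix)
            }),
            obj$initial_dist)
}

#' Write Viterbi paths run-length-encoded
#'
#' @param paths List of [viterbi()] paths.
#' @param path Output `.tsv` path.
#' @return Invisibly, `path`.
#' @export
write_paths <- function(paths, path) {
  con <- file(path, open = "wb")
  writeLines("trace_id\tpath_loglik\tstates_rle", con)
  ids <- vapply(paths, function(p) p$trace_id, character(1))
  for (p in paths[order(ids, method = "radix")]) {
    writeLines(sprintf("%s\t%.17g\t%s", p$trace_id, p$path_loglik,
                       rle_encode(p$states)), con)
  }
  close(con)
  invisible(path)
}

#' @rdname write_paths
#' @export
read_paths <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(trace_id = df$trace_id[i],
                   states = rle_decode(df$states_rle[i]),
                   path_loglik = df$path_loglik[i]),
              class = "smfret_path")
  })
}

#' Export a density curve or TDP grid as TSV
#'
#' Density curves are written as two columns (grid, density); TDP grids as
#' a matrix with axis headers. A provenance comment line (config hash,
#' seed) can be prepended.
#'
#' @param x An `smfret_density` or `smfret_tdp`.
#' @param path Output path.
#' @param provenance Optional string written as a leading `#` comment.
#' @return Invisibly, `path`.
#' @export
write_density_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, open = "wb")
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  if (inherits(x, "smfret_tdp")) {
    writeLines(paste(c("e_initial\\e_final", sprintf("%.6g", x$y)), collapse = "\t"), con)
    for (i in seq_along(x$x)) {
      writeLines(paste(c(sprintf("%.6g", x$x[i]), sprintf("%.10g", x$density[i, ])),
                       collapse = "\t"), con)
    }
  } else {
    writeLines("grid\tdensity", con)
    writeLines(sprintf("%.6g\t%.10g", x$grid, x$density), con)
  }
  close(con)
  invisible(path)
}
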