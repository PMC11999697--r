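#' Run configuration for the simulate/fit/report pipeline
#'
#' A fully serializable description of one reproducible run. May be built
#' from a named list or read from a JSON file. Recognized top-level keys
#' (all optional except `out_dir`):
#' \describe{
#'   \item{seed}{Master seed (default 1).}
#'   \item{scenarios}{Character vector of preset names (default
#'     `"apo-CXCR4"`).}
#'   \item{n_traces, n_frames}{Simulation size (defaults 150, 300).}
#'   \item{noise}{Named list of [noise_spec()] arguments.}
#'   \item{correction}{Named list of [correction_params()] arguments.}
#'   \item{screen}{Named list of [screen_config()] arguments.}
#'   \item{hmm}{Named list of [hmm_config()] arguments.}
#'   \item{candidate_Ks}{State counts to compare (default 2:5).}
#'   \item{n_states}{Fixed K; skips model selection when given.}
#'   \item{bandwidth}{Histogram kernel SD (default 0.04).}
#'   \item{tdp_sigma}{TDP kernel SD (default 0.03).}
#'   \item{compare}{List of 2-element character vectors: condition pairs to
#'     difference in the report.}
#'   \item{out_dir}{Output directory.}
#' }
#' Every output file of a run embeds the MD5 hash of the canonical config
#' JSON, so results are traceable to their configuration.
#'
#' @param config Named list or path to a JSON config file.
#' @return An object of class `smfret_run_config` with a `hash` attribute.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_parse("config file '%s' does not exist", config)
    path <- config
    config <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                       error = function(e) {
                         stop_parse("config file '%s' is not valid JSON: %s",
                                    path, conditionMessage(e))
                       })
    if (!is.null(config$compare) && is.matrix(config$compare)) {
      config$compare <- lapply(seq_len(nrow(config$compare)),
                               function(i) config$compare[i, ])
    }
  }
  defaults <- list(seed = 1L, scenarios = "apo-CXCR4", n_traces = 150L,
                   n_frames = 300L, noise = list(), correction = list(),
                   screen = list(), hmm = list(), candidate_Ks = 2:5,
                   n_states = NULL, bandwidth = 0.04, tdp_sigma = 0.03,
                   compare = NULL, out_dir = "smfret-run")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  cfg$seed <- check_count(cfg$seed, "seed")
  canon <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                            digits = NA, null = "null")
  tmp <- tempfile()
  writeLines(canon, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  structure(cfg, class = "smfret_run_config", hash = hash)
}

config_objects <- function(cfg) {
  list(noise = do.call(noise_spec, cfg$noise),
       correction = do.call(correction_params, cfg$correction),
       screen = do.call(screen_config, cfg$screen),
       hmm = do.call(hmm_config, cfg$hmm))
}

provenance <- function(cfg) {
  sprintf("config_hash=%s seed=%d", attr(cfg, "hash"), cfg$seed)
}

run_log <- function(...) message("[smfret] ", sprintf(...))

#' Simulate the configured scenarios and write trace files
#'
#' Writes, per scenario, the SMT-TSV trace file, its manifest, and a
#' ground-truth sidecar into `out_dir`.
#'
#' @param config A [run_config()] (or list/path accepted by it).
#' @return Invisibly, the written trace-file paths (named by scenario).
#' @export
run_simulate <- function(config = list()) {
  cfg <- if (inherits(config, "smfret_run_config")) config else run_config(config)
  obj <- config_objects(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (si in seq_along(cfg$scenarios)) {
    name <- cfg$scenarios[si]
    exp <- simulate_experiment(name, cfg$n_traces, cfg$n_frames, obj$noise,
                               seed = derive_seed(cfg$seed, si))
    base <- file.path(cfg$out_dir, gsub("[^A-Za-z0-9._-]", "_", name))
    write_traces(exp, paste0(base, ".tsv"),
                 extra = list(config_hash = attr(cfg, "hash"),
                              seed = cfg$seed, scenario = name))
    write_ground_truth(exp$truth, paste0(base, ".truth.tsv"))
    run_log("simulated scenario '%s': %d traces x %d frames", name,
            cfg$n_traces, cfg$n_frames)
    paths[name] <- paste0(base, ".tsv")
  }
  invisible(paths)
}

#' Screen, fit, and select state count for the configured scenarios
#'
#' Reads the trace files written by [run_simulate()] from `out_dir`,
#' corrects and screens them, fits the global HMM (either for the fixed
#' `n_states` or across `candidate_Ks` with BIC selection), and writes
#' per-condition model JSONs, Viterbi path files, and a selection summary.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the selection result and per-condition
#'   screened trajectories.
#' @export
run_fit <- function(config = list()) {
  cfg <- if (inherits(config, "smfret_run_config")) config else run_config(config)
  obj <- config_objects(cfg)
  trajs_by_cond <- list()
  for (name in cfg$scenarios) {
    base <- file.path(cfg$out_dir, gsub("[^A-Za-z0-9._-]", "_", name))
    traces <- read_traces(paste0(base, ".tsv"))
    scr <- screen_experiment(traces, obj$screen, obj$correction)
    if (!length(scr$trajectories)) {
      stop_data("screening left zero traces for condition '%s'", name)
    }
    run_log("condition '%s': %d/%d traces accepted", name,
            length(scr$trajectories), length(traces))
    trajs_by_cond[[name]] <- scr$trajectories
  }
  ks <- if (!is.null(cfg$n_states)) cfg$n_states else cfg$candidate_Ks
  sel <- select_state_count(trajs_by_cond, ks, obj$hmm, seed = cfg$seed,
                            bandwidth = cfg$bandwidth)
  ki <- as.character(sel$selected_K)
  for (name in cfg$scenarios) {
    base <- file.path(cfg$out_dir, gsub("[^A-Za-z0-9._-]", "_", name))
    write_model(sel$fits[[ki]][[name]], paste0(base, ".model.json"),
                extra = list(config_hash = attr(cfg, "hash"),
                             seed = cfg$seed, condition = name))
    write_paths(sel$paths[[name]], paste0(base, ".paths.tsv"))
  }
  jsonlite::write_json(
    list(config_hash = attr(cfg, "hash"), seed = cfg$seed,
         candidate_Ks = sel$candidate_Ks, selected_K = sel$selected_K,
         bic_total = as.list(stats::setNames(sel$bic_total,
                                             as.character(sel$candidate_Ks))),
         bic_by_condition = apply(sel$bic_table, 2L, identity, simplify = FALSE),
         peak_consistency = sel$peak_consistency, peak_flag = sel$peak_flag),
    file.path(cfg$out_dir, "selection.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  run_log("selected K = %d", sel$selected_K)
  invisible(list(selection = sel, trajectories = trajs_by_cond))
}

#' Summarize fitted runs: populations, histograms, TDPs, dwells, shifts
#'
#' Reads the fit artifacts written by [run_fit()] and writes, per
#' condition, population JSON, per-state histogram TSVs, a TDP grid TSV,
#' and a dwell-time table; plus a comparison JSON for each configured
#' condition pair. All outputs embed the config hash and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of per-condition summaries.
#' @export
run_report <- function(config = list()) {
  cfg <- if (inherits(config, "smfret_run_config")) config else run_config(config)
  obj <- config_objects(cfg)
  summaries <- list()
  pops <- list()
  for (name in cfg$scenarios) {
    base <- file.path(cfg$out_dir, gsub("[^A-Za-z0-9._-]", "_", name))
    if (!file.exists(paste0(base, ".model.json"))) {
      stop_data("fit artifacts missing for condition '%s' (run run_fit first)", name)
    }
    model <- read_model(paste0(base, ".model.json"))
    paths <- read_paths(paste0(base, ".paths.tsv"))
    traces <- read_traces(paste0(base, ".tsv"))
    scr <- screen_experiment(traces, obj$screen, obj$correction)
    trajs <- scr$trajectories
    K <- model$n_states
    pop <- state_populations(paths, K, condition = name)
    hists <- per_state_histograms(trajs, paths, K, cfg$bandwidth)
    events <- extract_transitions(trajs, paths)
    tdp <- build_tdp(events, cfg$tdp_sigma)
    dwells <- dwell_times(paths, K, trajs[[1L]]$frame_interval, condition = name)
    jsonlite::write_json(
      list(config_hash = attr(cfg, "hash"), seed = cfg$seed, condition = name,
           n_states = K, fractions = pop$fractions, n_frames = pop$n_frames,
           n_traces = pop$n_traces,
           dwell_summary = dwells$summary),
      paste0(base, ".populations.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write_density_tsv(hists$envelope, paste0(base, ".envelope.tsv"),
                      provenance = provenance(cfg))
    write_density_tsv(tdp, paste0(base, ".tdp.tsv"), provenance = provenance(cfg))
    pops[[name]] <- pop
    summaries[[name]] <- list(populations = pop, histograms = hists,
                              tdp = tdp, dwells = dwells)
    run_log("reported condition '%s'", name)
  }
  if (!is.null(cfg$compare)) {
    comps <- lapply(cfg$compare, function(pair) {
      cmp <- compare_conditions(pops[[pair[1L]]], pops[[pair[2L]]])
      list(condition_a = pair[1L], condition_b = pair[2L],
           delta_fractions = cmp$delta_fractions)
    })
    jsonlite::write_json(
      list(config_hash = attr(cfg, "hash"), seed = cfg$seed, comparisons = comps),
      file.path(cfg$out_dir, "comparisons.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  invisible(summaries)
}

#' Run simulate, fit, and report in sequence
#'
#' @param config A [run_config()].
#' @return Invisibly, the [run_report()] summaries.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "smfret_run_config")) config else run_config(config)
  run_simulate(cfg)
  run_fit(cfg)
  invisible(run_report(cfg))
}
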