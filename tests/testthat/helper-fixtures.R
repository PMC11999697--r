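# Shared fixtures. Heavyweight pipeline runs used by several acceptance
# checks are computed once per test session and cached in this environment.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# A two-state scenario with well-separated means, used wherever the test
# needs essentially error-free decoding.
two_state_scenario <- function(a_stay = 0.95, sigma = 0.05,
                               means = c(0.8, 0.2)) {
  scenario_spec("two-state", means,
                matrix(c(a_stay, 1 - a_stay, 1 - a_stay, a_stay), 2, 2,
                       byrow = TRUE),
                shared_sigma = sigma)
}

# FRET trajectories drawn directly from the emission model (no channel
# simulation), for tests of the HMM machinery in isolation.
simulate_fret_set <- function(spec, n_traces, n_frames, seed) {
  lapply(seq_len(n_traces), function(i) {
    path <- simulate_state_path(spec, n_frames, seed * 1000L + 2L * i)
    e <- spec$state_means[path]
    if (spec$shared_sigma > 0) {
      e <- e + smfret:::with_seed(seed * 1000L + 2L * i + 1L,
                                  rnorm(n_frames, 0, spec$shared_sigma))
    }
    fret_trajectory(sprintf("fret-%03d", i), e, spec$frame_interval)
  })
}

# Clean single-step trace: acceptor drops at `frame`, donor complements.
step_trace <- function(n = 400L, frame = 201L, hi = 500, lo = 20,
                       noise = 0, seed = 1L, id = "step") {
  acc <- c(rep(hi, frame - 1L), rep(lo, n - frame + 1L))
  don <- c(rep(480, frame - 1L), rep(960, n - frame + 1L))
  if (noise > 0) {
    smfret:::with_seed(seed, {
      acc <- acc + rnorm(n, 0, noise)
      don <- don + rnorm(n, 0, noise)
    })
  }
  intensity_trace(id, don, acc)
}

screened_trajectories <- function(scenario, n_traces, n_frames, seed) {
  screen_experiment(simulate_experiment(scenario, n_traces, n_frames,
                                        seed = seed))$trajectories
}

# Full-scale study-condition runs shared by the acceptance suite.
cxcr4_selection <- function() {
  cached("cxcr4_selection", {
    apo <- screened_trajectories("apo-CXCR4", 150, 300, seed = 101)
    ago <- screened_trajectories("CXCL12-CXCR4", 150, 300, seed = 102)
    list(sel = select_state_count(list("apo-CXCR4" = apo,
                                       "CXCL12-CXCR4" = ago),
                                  2:5, seed = 7),
         apo = apo, ago = ago)
  })
}

ackr3_selection <- function() {
  cached("ackr3_selection", {
    apo <- screened_trajectories("apo-ACKR3", 150, 300, seed = 103)
    ago <- screened_trajectories("CXCL12-ACKR3", 150, 300, seed = 104)
    list(sel = select_state_count(list("apo-ACKR3" = apo,
                                       "CXCL12-ACKR3" = ago),
                                  2:5, seed = 8),
         apo = apo, ago = ago)
  })
}
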