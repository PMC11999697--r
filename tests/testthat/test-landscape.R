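path_obj <- function(states, id = "p") {
  structure(list(trace_id = id, states = as.integer(states), path_loglik = 0),
            class = "smfret_path")
}

test_that("state populations are frame-weighted occupancies", {
  p <- state_populations(list(path_obj(c(1, 1, 2, 2))), 2)
  expect_equal(p$fractions, c(0.5, 0.5))
  p2 <- state_populations(list(path_obj(rep(1, 10))), 3)
  expect_equal(p2$fractions, c(1, 0, 0))
  expect_equal(sum(p2$fractions), 1)
  expect_error(state_populations(list(), 2), "at least one")
  expect_error(state_populations(list(path_obj(c(1, 4))), 3), "exceed")
})

test_that("decoded populations recover the near-uniform ACKR3 landscape", {
  scr <- screen_experiment(simulate_experiment("apo-ACKR3", 200, 300, seed = 71))
  fit <- em_fit(scr$trajectories, 4)
  pop <- state_populations(viterbi_all(scr$trajectories, fit$model), 4)
  expect_true(all(abs(pop$fractions - 0.25) < 0.05))
})

test_that("per-state curves sum pointwise to the envelope", {
  set.seed(72)
  trajs <- list(fret_trajectory("a", c(rnorm(60, 0.8, 0.05), rnorm(40, 0.2, 0.05))))
  paths <- list(path_obj(c(rep(1, 60), rep(2, 40)), "a"))
  h <- per_state_histograms(trajs, paths, 2)
  stacked <- h$state_curves[[1]]$density + h$state_curves[[2]]$density
  expect_lt(max(abs(stacked - h$envelope$density)), 1e-9)
  g <- h$envelope$grid
  integral <- sum(diff(g) * (h$envelope$density[-1] + h$envelope$density[-length(g)]) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  # peak positions near the generating means
  for (k in 1:2) {
    pk <- g[which.max(h$state_curves[[k]]$density)]
    expect_lt(abs(pk - c(0.8, 0.2)[k]), 0.02)
  }
  # all frames in one state: envelope equals that state's curve, other flagged
  h1 <- per_state_histograms(trajs, list(path_obj(rep(1, 100), "a")), 2)
  expect_equal(h1$state_curves[[1]]$density, h1$envelope$density)
  expect_equal(h1$empty_states, 2L)
})

test_that("transition events carry dwell-averaged raw FRET coordinates", {
  trajs <- list(fret_trajectory("a", c(0.8, 0.8, 0.2, 0.2)))
  paths <- list(path_obj(c(1, 1, 2, 2), "a"))
  ev <- extract_transitions(trajs, paths)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$from_state, 1L)
  expect_equal(ev$to_state, 2L)
  expect_equal(ev$e_from, 0.8)
  expect_equal(ev$e_to, 0.2)
  expect_equal(ev$dwell_before, 0.2)
  # constant path: no events
  ev0 <- extract_transitions(trajs, list(path_obj(rep(1, 4), "a")))
  expect_equal(nrow(ev0), 0L)
})

test_that("event count equals the number of label changes over all paths", {
  spec <- two_state_scenario(a_stay = 0.9)
  trajs <- simulate_fret_set(spec, 20, 100, seed = 73)
  model <- hmm_model(c(0.8, 0.2), 0.05^2, spec$transition_matrix, c(0.5, 0.5))
  paths <- viterbi_all(trajs, model)
  ev <- extract_transitions(trajs, paths)
  n_changes <- sum(vapply(paths, function(p) sum(diff(p$states) != 0), numeric(1)))
  expect_equal(nrow(ev), n_changes)
})

test_that("a two-event TDP has two mirror-symmetric off-diagonal peaks", {
  ev <- data.frame(trace_id = "t", from_state = c(1L, 2L), to_state = c(2L, 1L),
                   e_from = c(0.2, 0.8), e_to = c(0.8, 0.2), dwell_before = 1)
  tdp <- build_tdp(ev, smoothing_sigma = 0.03)
  expect_equal(nrow(tdp$peaks), 2L)
  expect_equal(sort(tdp$peaks$x), sort(tdp$peaks$y))
  expect_equal(sum(tdp$density) * diff(tdp$x[1:2])^2, 1, tolerance = 1e-3)
  # mirror symmetry of the grid itself
  expect_equal(tdp$density, t(tdp$density), tolerance = 1e-9)
  # zero events: flagged empty grid, not an error
  tdp0 <- build_tdp(ev[0, ])
  expect_true(tdp0$empty)
  expect_equal(tdp0$n_transitions, 0L)
})

test_that("mixed labeling yields four FRET levels but two cross-peak pairs", {
  ev <- mixed_labeling_events(seed = 74)
  expect_equal(sort(unique(ev$from_state)), 1:4)
  tdp <- build_tdp(ev)
  pairs <- tdp_cross_peak_pairs(tdp)
  expect_equal(nrow(pairs), 2L)
  expect_true(all(pairs$n_peaks == 2L))
  expect_equal(sort(round(pairs$low, 1)), c(0.2, 0.4))
  expect_equal(sort(round(pairs$high, 1)), c(0.6, 0.8))
})

test_that("sequential presets produce no non-adjacent TDP connectivity", {
  scr <- screen_experiment(simulate_experiment("apo-ACKR3", 120, 300, seed = 75))
  fit <- em_fit(scr$trajectories, 4)
  paths <- viterbi_all(scr$trajectories, fit$model)
  ev <- extract_transitions(scr$trajectories, paths)
  frac_nonadj <- mean(abs(ev$from_state - ev$to_state) > 1)
  expect_lte(frac_nonadj, 0.02)
  # and the TDP shows no peak for the non-adjacent R <-> R* pair
  tdp <- build_tdp(ev)
  mu <- fit$model$means
  if (nrow(tdp$peaks)) {
    d_r_rstar <- sqrt((tdp$peaks$x - mu[1])^2 + (tdp$peaks$y - mu[4])^2)
    expect_gt(min(d_r_rstar), 0.05)
  }
})

test_that("dwell censoring keeps interior runs only", {
  d <- dwell_times(list(path_obj(c(1, 2, 1))), 2)
  expect_equal(d$summary$count, c(0L, 1L))
  expect_equal(d$summary$mean_s[2], 0.1)
  expect_equal(d$empty_states, 1L)
})

test_that("decoded dwell means follow dt / (1 - A_ii) and are seconds-scale", {
  spec <- two_state_scenario(a_stay = 0.9, sigma = 0.05)
  trajs <- simulate_fret_set(spec, 60, 200, seed = 76)
  model <- hmm_model(c(0.8, 0.2), 0.05^2, spec$transition_matrix, c(0.5, 0.5))
  d <- dwell_times(viterbi_all(trajs, model), 2)
  for (k in 1:2) {
    n_k <- d$summary$count[k]
    expect_gt(n_k, 300)
    se <- 1.0 / sqrt(n_k) # exponential: SE of mean = mean / sqrt(n)
    expect_lt(abs(d$summary$mean_s[k] - 1.0), 3 * se)
  }
  # default preset dwells are in the seconds range
  scr <- screen_experiment(simulate_experiment("apo-ACKR3", 60, 300, seed = 77))
  fit <- em_fit(scr$trajectories, 4)
  dw <- dwell_times(viterbi_all(scr$trajectories, fit$model), 4)
  all_dwells <- unlist(dw$samples)
  expect_gte(median(all_dwells), 1.0)
})

test_that("condition comparisons report zero-sum percentage-point deltas", {
  pa <- state_populations(list(path_obj(c(1, 1, 1, 2))), 2, "a")
  pb <- state_populations(list(path_obj(c(1, 2, 2, 2))), 2, "b")
  cmp <- compare_conditions(pa, pb, groups = list(active = 2L))
  expect_equal(cmp$delta_fractions, c(-50, 50))
  expect_equal(sum(cmp$delta_fractions), 0, tolerance = 1e-9)
  expect_equal(cmp$group_deltas[["active"]], 50)
  same <- compare_conditions(pa, pa)
  expect_true(all(same$delta_fractions == 0))
  pc <- state_populations(list(path_obj(c(1, 2, 3))), 3, "c")
  expect_error(compare_conditions(pa, pc), "different state counts")
})
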