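test_that("absorbing chain yields a constant state path", {
  spec <- scenario_spec("absorbing", c(0.8, 0.2), diag(2),
                        initial_dist = c(1, 0))
  expect_equal(simulate_state_path(spec, 50, seed = 3), rep(1L, 50))
})

test_that("empirical transition frequencies match the generator", {
  spec <- two_state_scenario(a_stay = 0.95)
  path <- simulate_state_path(spec, 10000, seed = 42)
  stay <- path[-1] == path[-length(path)]
  expect_equal(mean(stay), 0.95, tolerance = 0.01 / 0.95)
  # full empirical matrix within 3 binomial SDs of each entry
  for (i in 1:2) {
    from_i <- which(path[-length(path)] == i)
    phat <- mean(path[from_i + 1L] == i)
    se <- sqrt(0.95 * 0.05 / length(from_i))
    expect_lt(abs(phat - 0.95), 3 * se + 1e-12)
  }
})

test_that("mean dwell follows dt / (1 - A_ii)", {
  spec <- two_state_scenario(a_stay = 0.9)
  path <- simulate_state_path(spec, 10000, seed = 11)
  r <- rle(path)
  dwells <- r$lengths[-c(1, length(r$lengths))] * spec$frame_interval
  expect_equal(mean(dwells), 1.0, tolerance = 0.1)
})

test_that("noiseless traces invert exactly to the state means", {
  spec <- scenario_spec("clean", c(0.8, 0.2),
                        matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                        shared_sigma = 0)
  noise <- noise_spec(channel_noise_sigma = 0, bleedthrough_alpha = 0,
                      acceptor_bleach_hazard = 0, simultaneous_bleach_hazard = 0)
  path <- simulate_state_path(spec, 100, seed = 5)
  sim <- simulate_trace(path, spec, noise, seed = 6)
  tr <- correct_intensities(sim$trace)
  fret <- compute_fret(tr)
  expect_equal(fret$e_app, spec$state_means[path], tolerance = 1e-12)
})

test_that("donor and acceptor are anti-correlated before the bleach", {
  spec <- two_state_scenario()
  path <- simulate_state_path(spec, 300, seed = 7)
  sim <- simulate_trace(path, spec, noise_spec(), seed = 8)
  bf <- sim$truth$bleach_frame
  pre <- 1:(bf - 1L)
  expect_lt(cor(sim$trace$donor[pre], sim$trace$acceptor[pre]), 0)
})

test_that("pre-bleach total intensity is conserved up to channel noise", {
  spec <- two_state_scenario()
  ns <- noise_spec(background_donor = 30, background_acceptor = 40,
                   bleedthrough_alpha = 0.1)
  path <- simulate_state_path(spec, 300, seed = 9)
  sim <- simulate_trace(path, spec, ns, seed = 10)
  pre <- 1:(sim$truth$bleach_frame - 1L)
  d <- sim$trace$donor[pre] - ns$background_donor
  a <- sim$trace$acceptor[pre] - ns$background_acceptor - ns$bleedthrough_alpha * d
  tot <- d + a
  expect_equal(mean(tot), ns$total_intensity, tolerance = 0.02)
  # coefficient of variation bounded by the two-channel noise prediction
  pred_cv <- sqrt(2) * ns$channel_noise_sigma / ns$total_intensity
  expect_lte(sd(tot) / mean(tot), 1.3 * pred_cv)
})

test_that("experiments are deterministic and support n_traces = 0", {
  e1 <- simulate_experiment("apo-CXCR4", 3, 80, seed = 12)
  e2 <- simulate_experiment("apo-CXCR4", 3, 80, seed = 12)
  expect_identical(e1$traces, e2$traces)
  expect_identical(e1$truth, e2$truth)
  e0 <- simulate_experiment("apo-CXCR4", 0, 80, seed = 12)
  expect_length(e0$traces, 0)
})

test_that("ground-truth occupancy matches the preset stationary distribution", {
  exp <- simulate_experiment("apo-ACKR3", 200, 300, seed = 13)
  states <- unlist(lapply(exp$truth, function(t) {
    n <- if (is.na(t$bleach_frame)) length(t$state_path) else t$bleach_frame - 1L
    t$state_path[1:n]
  }))
  occ <- tabulate(states, 4) / length(states)
  expect_true(all(abs(occ - 0.25) < 0.05))
})

test_that("bleach classes occur in proportion to the stated hazards", {
  ns <- noise_spec(acceptor_bleach_hazard = 0.006,
                   simultaneous_bleach_hazard = 0.002)
  exp <- simulate_experiment("apo-CXCR4", 1000, 120, noise = ns, seed = 14)
  cls <- vapply(exp$truth, function(t) t$bleach_class, character(1))
  p_hat <- mean(cls == "acceptor_only")
  p_true <- 0.006 / 0.008
  se <- sqrt(p_true * (1 - p_true) / length(cls))
  expect_lt(abs(p_hat - p_true), 3 * se)
  expect_setequal(unique(cls), c("acceptor_only", "simultaneous"))
})

test_that("bleach frames honor the pre/post minimum margins", {
  ns <- noise_spec(acceptor_bleach_hazard = 0.05, pre_bleach_frames_min = 25,
                   post_bleach_frames_min = 10)
  exp <- simulate_experiment("apo-CXCR4", 200, 100, noise = ns, seed = 15)
  bf <- vapply(exp$truth, function(t) t$bleach_frame, integer(1))
  expect_true(all(bf >= 26 & bf <= 91))
})
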