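test_that("intensity_trace enforces its invariants", {
  expect_error(intensity_trace("t", 1:5, 1:4), "equal length")
  expect_error(intensity_trace("t", c(1, 2), c(1, NA)), "finite")
  expect_error(intensity_trace("t", 1:10, 1:10, frame_interval = 0),
               "frame_interval")
  expect_error(intensity_trace("t", 1:10, 1:10, bleach_frame = 1), "bleach_frame")
  expect_error(intensity_trace("t", 1:10, 1:10, bleach_frame = 11), "bleach_frame")
})

test_that("intensity correction follows the stated formula", {
  tr <- intensity_trace("t", donor = rep(100, 10), acceptor = rep(60, 10))
  # identity when alpha and backgrounds are zero
  id <- correct_intensities(tr, correction_params())
  expect_equal(id$donor, tr$donor)
  expect_equal(id$acceptor, tr$acceptor)
  # worked example: acceptor' = 60 - 10 - 0.1 * 100 = 40
  out <- correct_intensities(tr, correction_params(0.1, 0, 10))
  expect_equal(out$donor, rep(100, 10))
  expect_equal(out$acceptor, rep(40, 10))
  # negative corrected intensities are allowed (no flooring)
  neg <- correct_intensities(intensity_trace("t", rep(100, 5), rep(50, 5)),
                             correction_params(0, 0, 100))
  expect_true(all(neg$acceptor == -50))
  # double application is a state error
  expect_error(correct_intensities(out, correction_params()), "already corrected")
})

test_that("correction inverts the simulator contamination exactly without noise", {
  spec <- two_state_scenario(sigma = 0)
  ns <- noise_spec(channel_noise_sigma = 0, bleedthrough_alpha = 0.15,
                   background_donor = 25, background_acceptor = 35,
                   acceptor_bleach_hazard = 0, simultaneous_bleach_hazard = 0)
  path <- simulate_state_path(spec, 60, seed = 2)
  sim <- simulate_trace(path, spec, ns, seed = 3)
  out <- correct_intensities(sim$trace,
                             correction_params(0.15, 25, 35))
  expect_equal(out$donor, ns$total_intensity * (1 - spec$state_means[path]),
               tolerance = 1e-9)
  expect_equal(out$acceptor, ns$total_intensity * spec$state_means[path],
               tolerance = 1e-9)
})

test_that("apparent FRET follows I_A / (I_A + I_D)", {
  mk <- function(d, a) {
    correct_intensities(intensity_trace("t", rep(d, 5), rep(a, 5)))
  }
  expect_equal(compute_fret(mk(100, 100))$e_app, rep(0.5, 5))
  expect_equal(compute_fret(mk(0, 50))$e_app, rep(1.0, 5))
  expect_equal(compute_fret(mk(150, 50))$e_app, rep(0.25, 5))
})

test_that("compute_fret truncates at the bleach and drops degenerate frames", {
  tr <- intensity_trace("t", donor = c(100, 100, 0, 100, 100),
                        acceptor = c(100, 100, 0, 100, 100),
                        bleach_frame = 5, corrected = TRUE)
  fret <- compute_fret(tr)
  expect_equal(fret$n_frames, 3L) # 4 pre-bleach frames, 1 degenerate dropped
  expect_equal(fret$n_dropped, 1L)
  expect_error(compute_fret(intensity_trace("t", rep(0, 4), rep(0, 4),
                                            corrected = TRUE)),
               "degenerate")
  expect_error(compute_fret(intensity_trace("t", 1:4, 1:4)), "corrected")
})

test_that("traces round-trip through the SMT-TSV exchange format", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "traces.tsv")
  exp <- simulate_experiment("apo-CXCR4", 3, 60, seed = 21)
  # ragged lengths: shorten one trace
  exp$traces[[2]] <- intensity_trace(exp$traces[[2]]$trace_id,
                                     exp$traces[[2]]$donor[1:40],
                                     exp$traces[[2]]$acceptor[1:40],
                                     bleach_frame = 30,
                                     bleach_class = "acceptor_only")
  write_traces(exp$traces, path)
  back <- read_traces(path)
  expect_length(back, 3)
  for (tr in exp$traces) {
    b <- back[[tr$trace_id]]
    expect_identical(b$donor, tr$donor)
    expect_identical(b$acceptor, tr$acceptor)
    expect_identical(b$bleach_frame, tr$bleach_frame)
    expect_identical(b$bleach_class, tr$bleach_class)
  }
  # writing twice is byte-identical
  path2 <- file.path(dir, "again.tsv")
  write_traces(exp$traces, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty collection: header-only data file plus valid manifest
  path0 <- file.path(dir, "empty.tsv")
  write_traces(list(), path0)
  expect_identical(readLines(path0), "trace_id\tframe_index\tdonor\tacceptor")
  expect_length(read_traces(path0), 0)
})

test_that("malformed trace files raise parse errors naming file and rule", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  writeLines(c("trace_id\tframe_index\tacceptor", "a\t0\t1"), path)
  writeLines('{"format_version":"1.0","frame_interval_s":0.1,"correction_state":"raw","traces":[]}',
             file.path(dir, "bad.manifest.json"))
  expect_error(read_traces(path), "missing column.*donor.*required-columns")
  path2 <- file.path(dir, "gap.tsv")
  writeLines(c("trace_id\tframe_index\tdonor\tacceptor",
               "a\t0\t1\t1", "a\t2\t1\t1"), path2)
  writeLines('{"format_version":"1.0","frame_interval_s":0.1,"correction_state":"raw","traces":[]}',
             file.path(dir, "gap.manifest.json"))
  expect_error(read_traces(path2), "contiguous-frames")
  expect_error(read_traces(file.path(dir, "nope.tsv")), "does not exist")
})

test_that("ground-truth sidecars round-trip including the RLE state path", {
  dir <- withr::local_tempdir()
  exp <- simulate_experiment("apo-ACKR3", 4, 80, seed = 22)
  p <- file.path(dir, "truth.tsv")
  write_ground_truth(exp$truth, p)
  back <- read_ground_truth(p)
  ids <- vapply(back, `[[`, character(1), "trace_id")
  for (t in exp$truth) {
    b <- back[[match(t$trace_id, ids)]]
    expect_identical(b$state_path, t$state_path)
    expect_identical(b$bleach_frame, t$bleach_frame)
    expect_identical(b$bleach_class, t$bleach_class)
  }
})
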