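test_that("init_model places means at pooled quantiles", {
  set.seed(1)
  # symmetric pooled data around 0.5: quantile means symmetric about 0.5
  vals <- c(rnorm(500, 0.3, 0.02), rnorm(500, 0.7, 0.02))
  tr <- fret_trajectory("t", vals)
  m2 <- init_model(list(tr), 2)
  expect_equal(m2$means[1] - 0.5, 0.5 - m2$means[2], tolerance = 0.01)
  m1 <- init_model(list(tr), 1)
  expect_equal(m1$means, median(vals))
  expect_equal(m1$transition_matrix, matrix(1, 1, 1))
  # deterministic
  expect_identical(init_model(list(tr), 3), init_model(list(tr), 3))
  expect_error(init_model(list(fret_trajectory("s", rnorm(15))), 2),
               "at least 20")
})

test_that("forward-backward matches brute-force path enumeration", {
  A <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  model <- hmm_model(c(0.8, 0.2), 0.05^2, A, c(0.6, 0.4))
  x <- c(0.75, 0.4, 0.25)
  fb <- forward_backward(fret_trajectory("t", x), model)
  expect_equal(fb$loglik,
               oracle_loglik(x, model$means, model$shared_variance, A,
                             model$initial_dist),
               tolerance = 1e-9)
  expect_equal(rowSums(fb$gamma), rep(1, 3), tolerance = 1e-12)
  # K = 1 closed form
  m1 <- hmm_model(0.5, 0.01, matrix(1), 1)
  fb1 <- forward_backward(fret_trajectory("t", x), m1)
  expect_equal(fb1$loglik, sum(dnorm(x, 0.5, 0.1, log = TRUE)), tolerance = 1e-10)
  expect_true(all(fb1$gamma == 1))
  # observations at a mean with tiny variance pin the posterior
  m_tiny <- hmm_model(c(0.8, 0.2), 1e-6, matrix(0.5, 2, 2), c(0.5, 0.5))
  fbt <- forward_backward(fret_trajectory("t", rep(0.8, 5)), m_tiny)
  expect_true(all(fbt$gamma[, 1] > 1 - 1e-10))
})

test_that("forward-backward oracle agreement holds across random tiny instances", {
  set.seed(7)
  for (rep in 1:10) {
    K <- sample(2:3, 1)
    T_ <- sample(3:6, 1)
    A <- matrix(runif(K * K, 0.05, 1), K)
    A <- A / rowSums(A)
    pi0 <- runif(K, 0.05, 1)
    pi0 <- pi0 / sum(pi0)
    means <- sort(runif(K, 0.1, 0.9), decreasing = TRUE)
    model <- hmm_model(means, 0.08^2, A, pi0)
    x <- runif(T_, 0, 1)
    fb <- forward_backward(fret_trajectory("t", x), model)
    expect_equal(fb$loglik, oracle_loglik(x, means, 0.08^2, A, pi0),
                 tolerance = 1e-9)
  }
})

test_that("viterbi matches exhaustive enumeration and the tie rule", {
  set.seed(8)
  for (rep in 1:10) {
    K <- sample(2:3, 1)
    T_ <- sample(4:8, 1)
    A <- matrix(runif(K * K, 0.05, 1), K)
    A <- A / rowSums(A)
    pi0 <- rep(1 / K, K)
    means <- sort(runif(K, 0.1, 0.9), decreasing = TRUE)
    model <- hmm_model(means, 0.08^2, A, pi0)
    x <- runif(T_, 0, 1)
    v <- viterbi(fret_trajectory("t", x), model)
    orc <- oracle_viterbi(x, means, 0.08^2, A, pi0)
    expect_equal(v$states, orc$path)
    expect_equal(v$path_loglik, orc$loglik, tolerance = 1e-9)
  }
  # equidistant observation, uniform A and initial distribution: lower index
  m <- hmm_model(c(0.7, 0.3), 0.01, matrix(0.5, 2, 2), c(0.5, 0.5))
  v <- viterbi(fret_trajectory("t", 0.5), m)
  expect_equal(v$states, 1L)
  # strong emissions at the second mean give a constant path at state 2
  v2 <- viterbi(fret_trajectory("t", rep(0.3, 6)), m)
  expect_equal(v2$states, rep(2L, 6))
})

test_that("global EM recovers two-state generator parameters", {
  spec <- two_state_scenario(a_stay = 0.95, sigma = 0.05, means = c(0.8, 0.2))
  trajs <- simulate_fret_set(spec, 100, 200, seed = 41)
  fit <- em_fit(trajs, 2)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$model$means - c(0.8, 0.2))), 0.02)
  expect_true(all(abs(diag(fit$model$transition_matrix) - 0.95) < 0.02))
  expect_lt(abs(sqrt(fit$model$shared_variance) - 0.05), 0.01)
  # loglik trajectory is monotone non-decreasing
  expect_true(all(diff(fit$loglik_trajectory) >= -1e-8))
})

test_that("parameter recovery is stable over twenty seeded replicates", {
  spec <- two_state_scenario(a_stay = 0.95, sigma = 0.05, means = c(0.8, 0.2))
  err_mean <- err_diag <- numeric(20)
  for (r in 1:20) {
    trajs <- simulate_fret_set(spec, 40, 150, seed = 500 + r)
    fit <- em_fit(trajs, 2)
    err_mean[r] <- max(abs(fit$model$means - c(0.8, 0.2)))
    err_diag[r] <- max(abs(diag(fit$model$transition_matrix) - 0.95))
    expect_true(all(diff(fit$loglik_trajectory) >= -1e-8))
  }
  expect_lte(median(err_mean), 0.01)
  expect_lte(median(err_diag), 0.02)
})

test_that("degenerate constant data hits the variance floor and is flagged", {
  trajs <- list(fret_trajectory("c", rep(0.5, 60)))
  fit <- em_fit(trajs, 2)
  expect_true(fit$variance_floored)
  expect_equal(fit$model$shared_variance, 1e-6)
  expect_equal(fit$model$means, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("permuting the initialization does not change the relabeled model", {
  spec <- two_state_scenario(a_stay = 0.9, sigma = 0.05)
  trajs <- simulate_fret_set(spec, 30, 120, seed = 43)
  f1 <- em_fit(trajs, 2, hmm_config(n_restarts = 1), seed = 1)
  f2 <- em_fit(trajs, 2, hmm_config(n_restarts = 4), seed = 99)
  expect_equal(f1$model$means, f2$model$means, tolerance = 1e-4)
  expect_equal(f1$model$transition_matrix, f2$model$transition_matrix,
               tolerance = 1e-3)
  # means strictly descending after the fit
  expect_true(all(diff(f1$model$means) < 0))
})

test_that("model_loglik is additive over disjoint trajectory sets", {
  spec <- two_state_scenario()
  trajs <- simulate_fret_set(spec, 6, 80, seed = 44)
  model <- hmm_model(c(0.8, 0.2), 0.0025, spec$transition_matrix, c(0.5, 0.5))
  expect_equal(model_loglik(trajs, model),
               model_loglik(trajs[1:3], model) + model_loglik(trajs[4:6], model),
               tolerance = 1e-9)
  expect_equal(model_loglik(trajs[1], model),
               forward_backward(trajs[[1]], model)$loglik)
})
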