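test_that("single-photon likelihood matches the closed form", {
  m <- random_h2mm_model(3)
  fb <- forward_backward(m, list(colors = 1, gaps = 0))
  expect_equal(fb$loglik,
               log(sum(m$initial_distribution * m$efficiencies)),
               tolerance = 1e-12)
  fb0 <- forward_backward(m, list(colors = 0, gaps = 0))
  expect_equal(fb0$loglik,
               log(sum(m$initial_distribution * (1 - m$efficiencies))),
               tolerance = 1e-12)
})

test_that("a frozen chain keeps all posterior mass on the start state", {
  # zero rate matrix -> identity per-tick transitions
  m <- h2mm_model(matrix(0, 3, 3), c(0.9, 0.5, 0.1),
                  initial_distribution = c(1, 0, 0), clock_period = 1e-6)
  fb <- forward_backward(m, list(colors = c(1, 1, 0, 1),
                                 gaps = c(0, 5, 3, 10)))
  expect_equal(fb$posteriors[, 1], rep(1, 4), tolerance = 1e-12)
  vit <- viterbi(m, list(colors = c(1, 1, 0, 1), gaps = c(0, 5, 3, 10)))
  expect_equal(vit$states, rep(1L, 4))
})

test_that("forward and Viterbi agree with exhaustive path enumeration", {
  set.seed(101)
  for (trial in 1:40) {
    K <- sample(2:3, 1)
    n <- sample(2:8, 1)
    m <- random_h2mm_model(K)
    colors <- sample(0:1, n, replace = TRUE)
    gaps <- c(0, sample(1:20, n - 1, replace = TRUE))
    T <- tick_matrix(m$rate_matrix, m$clock_period)
    B <- cbind(1 - m$efficiencies, m$efficiencies)
    fb <- forward_backward(m, list(colors = colors, gaps = gaps))
    expect_equal(fb$loglik,
                 brute_loglik(T, B, m$initial_distribution, colors, gaps),
                 tolerance = 1e-9)
    expect_equal(burst_loglik(m, list(colors = colors, gaps = gaps)),
                 fb$loglik, tolerance = 1e-12)
    expect_equal(max(abs(rowSums(fb$posteriors) - 1)), 0, tolerance = 1e-9)
    vit <- viterbi(m, list(colors = colors, gaps = gaps))
    oracle <- brute_viterbi(T, B, m$initial_distribution, colors, gaps)
    expect_equal(unname(vit$path_loglik), oracle$loglik, tolerance = 1e-9)
    expect_gte(oracle$loglik + 1e-9, vit$path_loglik)
  }
})

test_that("one-state EM recovers the pooled acceptor fraction exactly", {
  m <- ground_truth_model(matrix(0, 1, 1), 0.419, initial_distribution = 1)
  sim <- simulate_dataset(m, 100, seed = 6)
  data <- h2mm_data(sim$stream, sim$bursts)
  fit <- em_fit(data, K = 1, restarts = 1, max_iter = 10)
  expect_equal(fit$model$efficiencies, mean(data$colors), tolerance = 1e-9)
})

test_that("EM log-likelihood is non-decreasing and states sort by E", {
  sim <- simulate_dataset(two_state_model(), 150, seed = 13)
  data <- h2mm_data(sim$stream, sim$bursts)
  fit <- em_fit(data, K = 2, restarts = 2, seed = 5)
  trace <- fit$loglik_trace
  expect_true(all(diff(trace) >= -1e-9 * abs(trace[1])))
  expect_true(all(diff(fit$model$efficiencies) < 0))
  expect_equal(max(abs(rowSums(tick_matrix(fit$model$rate_matrix,
                                           fit$model$clock_period)) - 1)),
               0, tolerance = 1e-9)
})

test_that("two-state fit recovers efficiencies and exchange rates", {
  truth <- two_state_model(k12 = 2500, k21 = 1500, E = c(0.75, 0.25))
  sim <- simulate_dataset(truth, 600, seed = 17)
  data <- h2mm_data(sim$stream, sim$bursts)
  fit <- em_fit(data, K = 2, restarts = 3, seed = 2)
  expect_within(fit$model$efficiencies, c(0.75, 0.25), 0.02)
  Q <- fit$model$rate_matrix
  expect_lt(abs(Q[1, 2] - 2500), 0.25 * 2500)
  expect_lt(abs(Q[2, 1] - 1500), 0.25 * 1500)
  pi_fit <- steady_state(Q)
  expect_within(pi_fit, steady_state(truth$rate_matrix), 0.04)
})

test_that("global fit over two copies matches a single-dataset fit", {
  sim <- simulate_dataset(two_state_model(), 200, seed = 23)
  data <- h2mm_data(sim$stream, sim$bursts)
  single <- em_fit(data, K = 2, restarts = 1, seed = 1)
  joint <- global_fit(list(a = data, b = data), K = 2, restarts = 1,
                      seed = 1)
  expect_equal(joint$model$efficiencies, single$model$efficiencies,
               tolerance = 1e-4)
  # per-dataset models share emissions
  expect_identical(joint$models$a$efficiencies,
                   joint$models$b$efficiencies)
})

test_that("global fit pools emissions but keeps kinetics per dataset", {
  t1 <- two_state_model(k12 = 3000, k21 = 1000, E = c(0.8, 0.3))
  t2 <- two_state_model(k12 = 1000, k21 = 3000, E = c(0.8, 0.3))
  s1 <- simulate_dataset(t1, 400, seed = 31)
  s2 <- simulate_dataset(t2, 400, seed = 32)
  d1 <- h2mm_data(s1$stream, s1$bursts)
  d2 <- h2mm_data(s2$stream, s2$bursts)
  fit <- global_fit(list(one = d1, two = d2), K = 2, restarts = 2, seed = 3)
  expect_within(fit$models$one$efficiencies, c(0.8, 0.3), 0.03)
  pi1 <- steady_state(fit$models$one$rate_matrix)
  pi2 <- steady_state(fit$models$two$rate_matrix)
  expect_within(pi1, steady_state(t1$rate_matrix), 0.05)
  expect_within(pi2, steady_state(t2$rate_matrix), 0.05)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9 * abs(fit$loglik_trace[1])))
})

test_that("model JSON round-trips", {
  m <- random_h2mm_model(3)
  path <- withr::local_tempfile(fileext = ".json")
  write_h2mm_model(m, path)
  m2 <- read_h2mm_model(path)
  expect_equal(m2$rate_matrix, m$rate_matrix)
  expect_equal(m2$efficiencies, m$efficiencies)
  expect_equal(m2$clock_period, m$clock_period)
})

test_that("model-size report returns the comparison table", {
  sim <- simulate_dataset(two_state_model(), 120, seed = 41)
  data <- h2mm_data(sim$stream, sim$bursts)
  rep <- model_selection_report(data, K_values = 1:2, restarts = 1,
                                max_iter = 40, screen_iter = 10)
  expect_equal(rep$K, 1:2)
  expect_true(all(is.finite(rep$bic)))
  # dynamic two-state data prefers K = 2 over K = 1
  expect_lt(rep$bic[2], rep$bic[1])
})

test_that("moderate uniform background barely perturbs recovered E", {
  # 1 kHz/channel background against a 100 kHz burst rate; background is
  # not part of the emission model, so recovery degrades gracefully
  Q <- matrix(c(-2000, 2000, 2000, -2000), 2, 2, byrow = TRUE)
  gt <- ground_truth_model(Q, c(0.8, 0.2),
                           background_rates = c(D = 1000, A = 1000))
  sim <- simulate_dataset(gt, 400, seed = 53)
  fit <- em_fit(h2mm_data(sim$stream, sim$bursts), K = 2, restarts = 2,
                seed = 4)
  expect_within(fit$model$efficiencies, c(0.8, 0.2), 0.03)
})
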