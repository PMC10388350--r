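test_that("macrostate fixtures reproduce the printed stationary populations", {
  pops <- list(
    apo    = c(0.084, 0.551, 0.296, 0.070),
    atp    = c(0.048, 0.253, 0.584, 0.115),
    adp    = c(0.085, 0.446, 0.384, 0.085),
    atp_es = c(0.047, 0.047, 0.254, 0.652)
  )
  for (cond in names(pops)) {
    fx <- make_macrostate_fixture(cond)
    expect_equal(max(abs(rowSums(fx$rate_matrix))), 0, tolerance = 1e-9)
    pi <- steady_state(fx$rate_matrix)
    # pi Q = 0 to machine precision
    expect_lt(max(abs(pi %*% fx$rate_matrix)), 1e-12 * max(abs(fx$rate_matrix)))
    # printed populations (percent precision, unit-sum renormalized)
    expect_equal(pi, pops[[cond]], tolerance = 2e-3)
    expect_equal(fx$efficiencies, c(0.850, 0.608, 0.419, 0.213))
  }
  expect_error(make_macrostate_fixture("nonsense"))
})

test_that("fixture exchange relaxes on the stated submillisecond timescale", {
  fx <- make_macrostate_fixture("apo")
  ev <- sort(Re(eigen(fx$rate_matrix)$values))
  relax <- -1 / ev[ev < -1e-9]
  # k_ij = c pi_j has a single relaxation time 1/c ~ 333 us
  expect_equal(unname(relax), rep(1 / 3000, 3), tolerance = 1e-9)
  expect_gt(min(relax), 250e-6)
  expect_lt(max(relax), 500e-6)
})

test_that("state-path simulation matches exponential holding statistics", {
  # no transitions: a single full-duration segment
  Q0 <- matrix(0, 2, 2)
  p <- simulate_state_path(Q0, 1e-3, start_state = 2)
  expect_equal(p$states, 2L)
  expect_equal(p$times, 0)

  set.seed(4)
  k <- 2000
  Q <- matrix(c(-k, k, k, -k), 2, 2, byrow = TRUE)
  # mean first holding time over many paths = 1/k within 3 SE
  # (trajectory length 20/k leaves negligible censoring mass, e^-20)
  n <- 20000
  first_hold <- replicate(n, {
    p <- simulate_state_path(Q, 20 / k, start_state = 1)
    if (length(p$times) > 1) p$times[2] else p$duration
  })
  se <- (1 / k) / sqrt(n)
  expect_lt(abs(mean(first_hold) - 1 / k), 3 * se)
})

test_that("long-trajectory occupancies converge to the stationary vector", {
  set.seed(9)
  fx <- make_macrostate_fixture("apo")
  p <- simulate_state_path(fx$rate_matrix, 4, start_state = 1)
  bounds <- c(p$times, p$duration)
  occ <- vapply(1:4, function(s) {
    sum(diff(bounds)[p$states == s])
  }, 0) / p$duration
  expect_equal(occ, steady_state(fx$rate_matrix), tolerance = 0.03)
})

test_that("photon colors follow the state efficiencies", {
  # E = 1: every donor-excitation photon is acceptor-colored
  m1 <- ground_truth_model(matrix(0, 1, 1), 1, initial_distribution = 1)
  sim1 <- simulate_dataset(m1, 50, seed = 2)
  dex <- sim1$stream$slot == "Dex"
  expect_true(all(sim1$stream$channel[dex] == "A"))

  # static E = 0.419: pooled acceptor fraction within 3 binomial SE
  m2 <- ground_truth_model(matrix(0, 1, 1), 0.419, initial_distribution = 1)
  sim2 <- simulate_dataset(m2, 2000, seed = 3)
  dex2 <- sim2$stream$slot == "Dex"
  n <- sum(dex2)
  frac <- mean(sim2$stream$channel[dex2] == "A")
  expect_lt(abs(frac - 0.419), 3 * sqrt(0.419 * 0.581 / n))

  # photons per burst ~ rate * mean duration
  mean_dex <- mean(vapply(seq_len(nrow(sim2$bursts)), function(b) {
    sim2$bursts$n_dd[b] + sim2$bursts$n_da[b]
  }, 0))
  expected <- m2$photon_rate * m2$burst_duration_mean
  expect_equal(mean_dex, expected, tolerance = 0.1)
})

test_that("same seed gives identical datasets", {
  fx <- make_macrostate_fixture("atp")
  a <- simulate_dataset(fx, 50, seed = 77)
  b <- simulate_dataset(fx, 50, seed = 77)
  expect_identical(a$stream$timestamps, b$stream$timestamps)
  expect_identical(a$stream$channel, b$stream$channel)
  expect_identical(a$bursts, b$bursts)
  c <- simulate_dataset(fx, 50, seed = 78)
  expect_false(identical(a$stream$channel, c$stream$channel))
})

test_that("titration mixtures follow the Hill law", {
  fa <- make_macrostate_fixture("apo")
  fs <- make_macrostate_fixture("atp")
  n <- 400
  sims <- simulate_titration(c(0, 1.7, 1.7e4), hill_n = 2.9, hill_k = 1.7,
                             fa, fs, n, seed = 10)
  expect_true(all(sims[["0"]]$truth$macrostate == "apo"))
  expect_gt(mean(sims[["17000"]]$truth$macrostate == "sat"), 0.999)
  frac_mid <- mean(sims[["1.7"]]$truth$macrostate == "sat")
  expect_lt(abs(frac_mid - 0.5), 3 * sqrt(0.25 / n))
})
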