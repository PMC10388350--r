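fit_model_of <- function(gt) {
  h2mm_model(gt$rate_matrix, gt$efficiencies,
             clock_period = gt$clock_period)
}

test_that("recoloring preserves timestamps and is seed-deterministic", {
  gt <- two_state_model()
  sim <- simulate_dataset(gt, 80, seed = 3)
  m <- fit_model_of(gt)
  r1 <- recolor_dataset(m, sim$stream, sim$bursts, seed = 9)
  r2 <- recolor_dataset(m, sim$stream, sim$bursts, seed = 9)
  expect_identical(r1$stream$timestamps, sim$stream$timestamps)
  expect_identical(r1$stream$channel, r2$stream$channel)
  r3 <- recolor_dataset(m, sim$stream, sim$bursts, seed = 10)
  expect_false(identical(r1$stream$channel, r3$stream$channel))

  # a one-state E = 1 model recolors every donor-excitation photon acceptor
  m1 <- h2mm_model(matrix(0, 1, 1), 1, initial_distribution = 1)
  r4 <- recolor_dataset(m1, sim$stream, sim$bursts, seed = 1)
  dex <- sim$stream$slot == "Dex"
  expect_true(all(r4$stream$channel[dex] == "A"))
  expect_identical(r4$stream$channel[!dex], sim$stream$channel[!dex])
})

test_that("recoloring under the true model reproduces the FRET histogram", {
  fx <- make_macrostate_fixture("apo")
  sim <- simulate_dataset(fx, 800, seed = 19)
  rec <- recolor_dataset(fit_model_of(fx), sim$stream, sim$bursts, seed = 4)
  h_obs <- fret_histogram(sim$bursts, n_bins = 10)
  h_rec <- fret_histogram(rec$bursts, n_bins = 10)
  # per-bin agreement within 3 sigma Poisson
  resid <- abs(h_obs$count - h_rec$count) /
    sqrt(pmax(h_obs$count + h_rec$count, 1))
  expect_lt(max(resid), 3)
})

test_that("dwell times match the exponential holding time of the chain", {
  # long bursts at a photon flux that resolves individual dwells
  gt <- two_state_model(k12 = 2000, k21 = 2000, burst_duration_mean = 5e-3,
                        photon_rate = 2.5e5)
  sim <- simulate_dataset(gt, 300, seed = 7)
  m <- fit_model_of(gt)
  dw <- weighted_dwell_times(m, h2mm_data(sim$stream, sim$bursts))
  # holding time 1/2000 = 500 us, both states, within 10%
  expect_within(dw$summary$tau_s, rep(5e-4, 2), 5e-5)
  expect_equal(dw$summary$tau_analytic_s, rep(5e-4, 2))
  expect_true(all(dw$summary$weight_sum > 0))
  expect_true(all(dw$dwells$duration_s >= 0))
})

test_that("apo fixture dwell analysis reports the analytic means", {
  fx <- make_macrostate_fixture("apo")
  sim <- simulate_dataset(fx, 400, seed = 29)
  dw <- weighted_dwell_times(fit_model_of(fx),
                             h2mm_data(sim$stream, sim$bursts))
  # fixture algebra: state 1 analytic dwell = 1/(c (1 - pi_1)) ~ 364 us
  expect_equal(dw$summary$tau_analytic_s[1],
               1 / (3000 * (1 - 0.0839)), tolerance = 1e-3)
  expect_true(all(dw$summary$n_dwells > 0))
  # at this photon flux decoded segmentation misses dwells shorter than the
  # path-probability resolution, so fitted means overestimate (documented
  # limitation) but never undershoot the analytic means
  expect_true(all(dw$summary$tau_s > dw$summary$tau_analytic_s))
})

test_that("a transition-free model yields only censored dwells", {
  m <- h2mm_model(matrix(0, 2, 2), c(0.8, 0.2),
                  initial_distribution = c(0.5, 0.5))
  gt <- two_state_model(k12 = 1e-9, k21 = 1e-9)
  sim <- simulate_dataset(gt, 50, seed = 11)
  dw <- weighted_dwell_times(m, h2mm_data(sim$stream, sim$bursts))
  # every burst is one segment touching both edges -> no uncensored dwells
  expect_true(all(dw$summary$flagged))
  expect_true(all(is.na(dw$summary$tau_s)))
})

test_that("single-state trajectories group by state with matching mean E", {
  fx <- make_macrostate_fixture("apo")
  sim <- simulate_dataset(fx, 1000, seed = 37)
  # shot-noise-limited group means need adequately bright bursts
  bursts <- sim$bursts[sim$bursts$n_dd + sim$bursts$n_da >= 60, ]
  data <- h2mm_data(sim$stream, bursts)
  sh <- segment_histograms(fit_model_of(fx), data, bursts)
  pop <- sh$groups$n_bursts >= 30
  expect_true(any(pop))
  expect_within(sh$groups$mean_e[pop], fx$efficiencies[pop], 0.03)

  # static data: every burst is single-state
  m1g <- ground_truth_model(matrix(0, 1, 1), 0.5, initial_distribution = 1)
  sim1 <- simulate_dataset(m1g, 40, seed = 5)
  d1 <- h2mm_data(sim1$stream, sim1$bursts)
  sh1 <- segment_histograms(h2mm_model(matrix(0, 1, 1), 0.5,
                                       initial_distribution = 1),
                            d1, sim1$bursts)
  expect_equal(sh1$groups$n_bursts, d1$n_bursts)

  # very fast exchange leaves few single-state trajectories
  fast <- two_state_model(k12 = 1e5, k21 = 1e5)
  simf <- simulate_dataset(fast, 200, seed = 41)
  shf <- segment_histograms(fit_model_of(fast),
                            h2mm_data(simf$stream, simf$bursts), simf$bursts)
  expect_lt(sum(shf$groups$n_bursts), 0.25 * 200)
})

test_that("correlation of static data is flat", {
  m <- ground_truth_model(matrix(0, 1, 1), 0.5, initial_distribution = 1,
                          burst_duration_mean = 3e-3)
  sim <- simulate_dataset(m, 500, seed = 13)  # ~1.5e5 Dex photons
  data <- h2mm_data(sim$stream, sim$bursts)
  for (pair in c("DxD", "DxA")) {
    g <- burstwise_fcs(data, pair, lag_min = 1e-5, lag_max = 1e-3)
    expect_lt(max(abs(g$G - 1)), 0.02)
  }
})

test_that("two-state exchange shows up at the right correlation time", {
  gt <- two_state_model(k12 = 2000, k21 = 2000, E = c(0.8, 0.2),
                        burst_duration_mean = 3e-3)
  sim <- simulate_dataset(gt, 1500, seed = 43)
  data <- h2mm_data(sim$stream, sim$bursts)
  g <- burstwise_fcs(data, "DxA", lag_min = 2e-5, lag_max = 3e-3)
  fitc <- fcs_relaxation_time(g)
  # donor-acceptor cross-correlation is anti-correlated by exchange
  expect_lt(fitc$amplitude, 0)
  # characteristic time 1/(k12 + k21) = 250 us within 30%
  expect_lt(abs(fitc$tau_c - 2.5e-4) / 2.5e-4, 0.3)
  # departure from 1 is localized below ~1 ms
  tail_g <- g$G[g$lag_s > 1.5e-3]
  expect_lt(max(abs(tail_g - 1)), 0.05)
})

test_that("apo-fixture exchange localizes correlation departure below 1 ms", {
  sim <- simulate_condition("apo", 1000, 101)
  g <- burstwise_fcs(sim$data, "DxA", lag_min = 1e-5, lag_max = 1e-2)
  # anti-correlation dip at short lags, relaxed by ~3x the 333 us timescale
  expect_lt(mean(g$G[g$lag_s < 3e-5]), 0.97)
  expect_within(g$G[g$lag_s > 1.2e-3], 1, 0.05)
})
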