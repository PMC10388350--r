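apo_model <- function() {
  fx <- make_macrostate_fixture("apo")
  h2mm_model(fx$rate_matrix, fx$efficiencies, clock_period = fx$clock_period)
}
atp_model <- function() {
  fx <- make_macrostate_fixture("atp")
  h2mm_model(fx$rate_matrix, fx$efficiencies, clock_period = fx$clock_period)
}

test_that("identical macrostate models score exactly one half", {
  sim <- simulate_dataset(make_macrostate_fixture("apo"), 30, seed = 3)
  data <- h2mm_data(sim$stream, sim$bursts)
  m <- apo_model()
  expect_equal(macrostate_score(data, m, m), rep(0.5, data$n_bursts))
})

test_that("swapping the models mirrors the score", {
  sim <- simulate_dataset(make_macrostate_fixture("atp"), 40, seed = 5)
  data <- h2mm_data(sim$stream, sim$bursts)
  s_fwd <- macrostate_score(data, apo_model(), atp_model())
  s_rev <- macrostate_score(data, atp_model(), apo_model())
  expect_equal(s_fwd + s_rev, rep(1, data$n_bursts), tolerance = 1e-12)
})

test_that("long labeled bursts are classified toward their macrostate", {
  # one transit samples only a few exchange correlation times, so per-burst
  # evidence grows slowly; 40 ms trajectories carry enough to classify
  sim_a <- simulate_dataset(
    make_macrostate_fixture("apo", burst_duration_mean = 40e-3), 120, seed = 7)
  sim_t <- simulate_dataset(
    make_macrostate_fixture("atp", burst_duration_mean = 40e-3), 120, seed = 8)
  d_a <- h2mm_data(sim_a$stream, sim_a$bursts)
  d_t <- h2mm_data(sim_t$stream, sim_t$bursts)
  s_a <- macrostate_score(d_a, apo_model(), atp_model())
  s_t <- macrostate_score(d_t, apo_model(), atp_model())
  long_a <- (d_a$bstop - d_a$bstart) >= 1000
  long_t <- (d_t$bstop - d_t$bstart) >= 1000
  expect_gt(sum(long_a), 50)
  expect_gt(mean(s_a[long_a] < 0.5), 0.9)
  expect_gt(mean(s_t[long_t] > 0.5), 0.9)
})

test_that("scaled scores recover mixture fractions linearly", {
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  n <- 500
  set.seed(11)
  sims_a <- simulate_dataset(
    make_macrostate_fixture("apo", burst_duration_mean = 5e-3), n, seed = 21)
  sims_t <- simulate_dataset(
    make_macrostate_fixture("atp", burst_duration_mean = 5e-3), n, seed = 22)
  s_a <- macrostate_score(h2mm_data(sims_a$stream, sims_a$bursts),
                          apo_model(), atp_model())
  s_t <- macrostate_score(h2mm_data(sims_t$stream, sims_t$bursts),
                          apo_model(), atp_model())
  scores <- lapply(fracs, function(f) {
    k <- round(f * n)
    c(sample(s_t, k, replace = TRUE), sample(s_a, n - k, replace = TRUE))
  })
  names(scores) <- as.character(seq_along(fracs) - 1)  # fake conc labels
  curve <- saturation_curve(scores = scores,
                            conc = c(0, 0.25, 0.5, 0.75, 1) * 4,
                            n_boot = 200, seed = 1)
  expect_equal(curve$score[1], 0)
  expect_equal(curve$score[5], 1)
  expect_within(curve$score, fracs, 0.1)
  expect_true(all(curve$se > 0))
})

test_that("saturation curve demands a zero-concentration endpoint", {
  scores <- list(`1` = runif(50), `2` = runif(50), `5` = runif(50),
                 `10` = runif(50))
  expect_error(saturation_curve(scores = scores), "zero-concentration")
})

test_that("noise-free Hill points are recovered exactly", {
  conc <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 5, 10)
  pts <- data.frame(conc_uM = conc,
                    score = hill_law(conc, 2.9, 1.7),
                    se = rep(0.01, length(conc)))
  fit <- hill_fit(pts)
  expect_equal(fit$n_hill, 2.9, tolerance = 1e-6)
  expect_equal(fit$k_app, 1.7, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$baseline, 0, tolerance = 1e-6)
})

test_that("a hyperbolic (n = 1) curve is half-saturated at K", {
  expect_equal(hill_law(1.7, 1, 1.7), 0.5)
  conc <- c(0, 0.2, 0.5, 1, 2, 5, 20)
  pts <- data.frame(conc_uM = conc, score = hill_law(conc, 1, 2),
                    se = rep(0.01, length(conc)))
  fit <- hill_fit(pts)
  expect_equal(fit$n_hill, 1, tolerance = 1e-5)
  expect_equal(hill_law(fit$k_app, fit$n_hill, fit$k_app), 0.5)
})

test_that("Hill fitting is concentration-scale equivariant", {
  conc <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 5, 10)
  set.seed(3)
  y <- hill_law(conc, 2.5, 1.4) + rnorm(length(conc), 0, 0.01)
  pts1 <- data.frame(conc_uM = conc, score = y, se = rep(0.02, length(conc)))
  pts2 <- data.frame(conc_uM = conc * 100, score = y,
                     se = rep(0.02, length(conc)))
  f1 <- hill_fit(pts1)
  f2 <- hill_fit(pts2)
  expect_equal(f2$n_hill, f1$n_hill, tolerance = 1e-4)
  expect_equal(f2$k_app, f1$k_app * 100, tolerance = 1e-3)
})

test_that("the synthetic titration pipeline traces a monotone Hill curve", {
  res <- run_titration_recovery(conc = c(0, 0.5, 1, 1.5, 2, 3, 10),
                                n_bursts_per_conc = 400, seed = 5,
                                n_boot = 200)
  sc <- res$curve$score
  # monotone within noise: strongly rank-correlated with concentration
  expect_gt(cor(sc, seq_along(sc), method = "spearman"), 0.85)
  expect_equal(sc[1], 0)
  expect_equal(sc[length(sc)], 1)
  expect_gt(res$hill$n_hill, 1.5)
})
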