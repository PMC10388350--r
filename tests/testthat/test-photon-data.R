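test_that("photon stream round-trips through the columnar text format", {
  s <- photon_stream(c(10, 250, 251), c("D", "A", "A"),
                     c("Dex", "Dex", "Aex"), clock_period = 12.5e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_photon_stream(s, path)
  s2 <- read_photon_stream(path)
  expect_identical(s2$timestamps, s$timestamps)
  expect_identical(s2$channel, s$channel)
  expect_identical(s2$slot, s$slot)
  expect_equal(s2$clock_period, s$clock_period)
})

test_that("columnar text with a plain header parses", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,channel,slot", "5,D,Dex", "9,A,Aex"), path)
  s <- read_photon_stream(path)
  expect_length(s, 2)
  expect_equal(s$timestamps, c(5, 9))
  expect_equal(s$channel, c("D", "A"))
})

test_that("invalid streams are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,channel", "5,D"), path)
  expect_error(read_photon_stream(path), "slot")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,channel,slot", "5,D,Dex", "3,A,Dex"), path2)
  expect_error(read_photon_stream(path2), "sorted")
  expect_error(photon_stream(1, "X", "Dex"), "channel")
  expect_error(photon_stream(1, "D", "Dex", clock_period = 0), "clock_period")
})

make_cluster_stream <- function(cluster_starts_s, n_photons = 100,
                                spacing_s = 1e-5, clock_period = 12.5e-9) {
  tt <- unlist(lapply(cluster_starts_s, function(t0) {
    t0 + spacing_s * (seq_len(n_photons) - 1)
  }))
  ticks <- round(tt / clock_period)
  photon_stream(ticks, rep("D", length(ticks)), rep("Dex", length(ticks)),
                clock_period = clock_period)
}

test_that("burst search finds nothing in a sparse uniform stream", {
  ticks <- round(seq(0, 1, by = 1e-3) / 12.5e-9)  # 1 kHz
  s <- photon_stream(ticks, rep("D", length(ticks)),
                     rep("Dex", length(ticks)))
  expect_equal(nrow(burst_search(s, 10, 5e4, 30)), 0)
})

test_that("burst search isolates dense photon clusters exactly", {
  # 100 photons at 100 kHz flanked by millisecond-scale empty time
  s <- make_cluster_stream(1e-3)
  b <- burst_search(s, window_m = 10, rate_threshold = 5e4, min_size = 30)
  expect_equal(nrow(b), 1)
  expect_equal(b$stop - b$start, 100)
  # local rate inside the found burst clears the threshold (direct check)
  idx <- b$start[1]:(b$stop[1] - 1)
  span <- diff(range(s$timestamps[idx])) * s$clock_period
  expect_gte((length(idx) - 1) / span, 5e4)

  s2 <- make_cluster_stream(c(1e-3, 11e-3))
  b2 <- burst_search(s2, 10, 5e4, 30)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$start, c(1L, 101L))
  expect_equal(b2$stop, c(101L, 201L))
})

test_that("burst search is invariant to empty flanking time and disjoint", {
  set.seed(7)
  fx <- make_macrostate_fixture("apo")
  sim <- simulate_dataset(fx, 30, seed = 21)
  b0 <- burst_search(sim$stream, 10, 5e4, 30)
  shifted <- photon_stream(sim$stream$timestamps + 1e7,
                           sim$stream$channel, sim$stream$slot,
                           clock_period = sim$stream$clock_period)
  b1 <- burst_search(shifted, 10, 5e4, 30)
  expect_equal(b1$start, b0$start)
  expect_equal(b1$stop, b0$stop)
  if (nrow(b0) > 1) {
    expect_true(all(b0$start[-1] >= b0$stop[-nrow(b0)]))
  }
})

test_that("burst quantities follow the counting formulas", {
  ch <- c(rep("D", 5), rep("A", 5), rep("A", 10))
  sl <- c(rep("Dex", 10), rep("Aex", 10))
  s <- photon_stream(seq_len(20) * 100, ch, sl)
  b <- fretstates:::burst_table(1L, 21L)
  b <- compute_burst_quantities(s, b)
  expect_equal(b$n_dd, 5)
  expect_equal(b$n_da, 5)
  expect_equal(b$n_aa, 10)
  expect_equal(b$e_raw, 0.5)
  expect_equal(b$s_raw, 0.5)
  expect_equal(b$e_corr, b$e_raw)  # identity corrections

  # all-donor burst: E = 0
  s2 <- photon_stream(seq_len(20) * 100, rep("D", 20), rep("Dex", 20))
  b2 <- compute_burst_quantities(s2, fretstates:::burst_table(1L, 21L))
  expect_equal(b2$e_raw, 0)

  # no donor-excitation photons: flagged, efficiency undefined
  s3 <- photon_stream(seq_len(5) * 100, rep("A", 5), rep("Aex", 5))
  b3 <- compute_burst_quantities(s3, fretstates:::burst_table(1L, 6L))
  expect_true(b3$flagged)
  expect_true(is.na(b3$e_raw))
})

test_that("e_raw is invariant under uniform time translation", {
  fx <- make_macrostate_fixture("apo")
  sim <- simulate_dataset(fx, 20, seed = 5)
  shifted <- photon_stream(sim$stream$timestamps + 12345,
                           sim$stream$channel, sim$stream$slot,
                           clock_period = sim$stream$clock_period)
  b2 <- compute_burst_quantities(shifted, sim$bursts)
  expect_equal(b2$e_raw, sim$bursts$e_raw)
})

test_that("stoichiometry filter keeps the window and preserves order", {
  b <- fretstates:::burst_table(c(1L, 11L, 21L), c(11L, 21L, 31L))
  b$s_raw <- c(0.1, 0.5, 0.95)
  b$e_raw <- 0.5
  kept <- stoichiometry_filter(b, 0.3, 0.8)
  expect_equal(kept$s_raw, 0.5)
  all_kept <- stoichiometry_filter(b, 0, 1)
  expect_equal(all_kept$s_raw, b$s_raw)
  expect_equal(nrow(stoichiometry_filter(b[0, ], 0.3, 0.8)), 0)
  expect_error(stoichiometry_filter(b, 0.9, 0.2), "s_min")
})

test_that("FRET histograms conserve burst counts", {
  b <- data.frame(e_raw = rep(0.5, 10), flagged = FALSE)
  h <- fret_histogram(b, n_bins = 10)
  expect_equal(sum(h$count), 10)
  expect_equal(sum(h$count > 0), 1)
  expect_equal(h$bin_left[h$count > 0], 0.5)

  set.seed(2)
  b2 <- data.frame(e_raw = runif(137), flagged = FALSE)
  h2 <- fret_histogram(b2, n_bins = 17)
  expect_equal(sum(h2$count), 137)
  expect_equal(sum(h2$density * diff(c(h2$bin_left, 1))), 1, tolerance = 1e-12)
})

test_that("apo-condition histogram peaks near the broad major mode", {
  sim <- simulate_dataset(make_macrostate_fixture("apo"), 800, seed = 31)
  h <- fret_histogram(sim$bursts, n_bins = 20)
  peak <- h$bin_center[which.max(h$count)]
  expect_gte(peak, 0.5)
  expect_lte(peak, 0.6)
})
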