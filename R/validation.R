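#' Photon recoloring under a fitted model
#'
#' The first validation of a fitted photon-by-photon HMM: keep every
#' measured photon arrival time, but redraw the photon colors from the
#' model — per burst a fresh hidden path is sampled (initial state from the
#' model's initial distribution, state transitions through `T^dt` between
#' photon arrivals) and each donor-excitation photon's channel is drawn
#' from the state's emission probabilities. Overlaying the recolored FRET
#' histogram on the measured one shows whether the model reproduces the
#' shape of the data. Acceptor-excitation photons are untouched.
#'
#' @param model an [h2mm_model()].
#' @param stream a [photon_stream].
#' @param bursts a filled burst table for `stream`.
#' @param seed integer seed; recoloring is deterministic given
#'   `(model, stream, bursts, seed)`.
#' @return A list with `stream` (same timestamps, redrawn channels),
#'   `bursts` (quantities recomputed) and `states` (the sampled hidden
#'   state per donor-excitation photon, for diagnostics).
#' @export
recolor_dataset <- function(model, stream, bursts, seed = 1L) {
  stopifnot(inherits(model, "h2mm_model"), inherits(stream, "photon_stream"))
  set.seed(seed)
  K <- model$n_states
  T1 <- tick_transition(model$rate_matrix, model$clock_period)
  eT <- eigen(T1)
  Vinv <- solve(eT$vectors)
  p0 <- model$initial_distribution
  E <- model$efficiencies
  channel <- stream$channel
  states_out <- rep(NA_integer_, length(stream$timestamps))
  step_probs <- function(state, dt) {
    row <- Re((eT$vectors[state, ] * eT$values^dt) %*% Vinv)
    row[row < 0] <- 0
    row / sum(row)
  }
  for (b in seq_len(nrow(bursts))) {
    idx <- bursts$start[b]:(bursts$stop[b] - 1L)
    dex <- idx[stream$slot[idx] == "Dex"]
    if (!length(dex)) next
    tk <- stream$timestamps[dex]
    s <- sample.int(K, 1, prob = p0)
    states <- integer(length(dex))
    states[1] <- s
    if (length(dex) > 1) {
      for (i in 2:length(dex)) {
        s <- sample.int(K, 1, prob = step_probs(s, tk[i] - tk[i - 1]))
        states[i] <- s
      }
    }
    channel[dex] <- ifelse(stats::runif(length(dex)) < E[states], "A", "D")
    states_out[dex] <- states
  }
  new_stream <- photon_stream(stream$timestamps, channel, stream$slot,
                              clock_period = stream$clock_period,
                              metadata = c(stream$metadata,
                                           list(recolored = TRUE)))
  list(stream = new_stream,
       bursts = compute_burst_quantities(new_stream, burst_table(
         bursts$start, bursts$stop)),
       states = states_out)
}

#' Likelihood-weighted dwell-time analysis
#'
#' The second validation: dwell durations of the decoded (Viterbi) state
#' segments are accumulated per state, each segment weighted by its
#' posterior support (the mean per-photon posterior probability of the
#' assigned state over the segment's photons). Edge segments — those
#' touching a burst boundary, whose durations are censored by the finite
#' transit — are excluded from the fit. The per-state monoexponential mean
#' is the weighted maximum-likelihood estimate (weighted mean of uncensored
#' dwells) and is reported next to the analytic mean `1 / (-Q[i, i])` of
#' the fitted rate matrix; agreement of the two is the consistency check.
#'
#' @param model an [h2mm_model()].
#' @param data a `photon_set` from [h2mm_data()].
#' @return An object of class `"dwell_time_result"`: `dwells` (segment
#'   table with weights), `summary` (per state: `tau_s` fitted mean,
#'   `tau_analytic_s`, `weight_sum`, `n_dwells`, `flagged` when a state has
#'   no uncensored dwells).
#' @export
weighted_dwell_times <- function(model, data) {
  vit <- viterbi(model, data)
  fb <- forward_backward(model, data)
  seg <- vit$segments
  # posterior support: mean posterior of the assigned state over the
  # segment's photons
  support <- numeric(nrow(seg))
  for (b in seq_along(data$bstart)) {
    seg_b <- which(seg$burst == b)
    off <- data$bstart[b]
    ph <- 0L
    for (s in seg_b) {
      rng <- off + ph + seq_len(seg$n_photons[s])
      support[s] <- mean(fb$posteriors[cbind(rng, seg$state[s])])
      ph <- ph + seg$n_photons[s]
    }
  }
  seg$weight <- support
  K <- model$n_states
  tau <- rep(NA_real_, K)
  wsum <- numeric(K)
  ndw <- integer(K)
  for (i in seq_len(K)) {
    use <- seg$state == i & !seg$edge
    ndw[i] <- sum(use)
    wsum[i] <- sum(seg$weight[use])
    if (wsum[i] > 0) {
      tau[i] <- sum(seg$weight[use] * seg$duration_s[use]) / wsum[i]
    }
  }
  structure(
    list(dwells = seg,
         summary = data.frame(
           state = seq_len(K), tau_s = tau,
           tau_analytic_s = 1 / (-diag(model$rate_matrix)),
           weight_sum = wsum, n_dwells = ndw,
           flagged = ndw == 0)),
    class = "dwell_time_result"
  )
}

#' @export
print.dwell_time_result <- function(x, ...) {
  cat("<dwell_time_result>\n")
  print(x$summary)
  invisible(x)
}

#' Per-state FRET histograms from single-state trajectories
#'
#' The third validation: bursts whose decoded state path occupies exactly
#' one state are grouped by that state, and the burst-averaged FRET
#' efficiency histogram of each group is returned. If the model is right,
#' each group's distribution is the shot-noise-limited peak of one
#' microstate. Groups are ordered by decreasing state efficiency (the
#' canonical state order).
#'
#' @param model an [h2mm_model()].
#' @param data a `photon_set` from [h2mm_data()].
#' @param bursts the burst table `data` was built from (for `e_raw`).
#' @param n_bins histogram bins.
#' @return A list with `assignments` (per analyzed burst: the single state
#'   or `NA`), `groups` (per state: `n_bursts`, `mean_e`), `histograms`
#'   (list of [fret_histogram()] tables by state).
#' @export
segment_histograms <- function(model, data, bursts, n_bins = 40) {
  vit <- viterbi(model, data)
  K <- model$n_states
  single <- rep(NA_integer_, data$n_bursts)
  for (b in seq_len(data$n_bursts)) {
    st <- unique(vit$states[(data$bstart[b] + 1L):data$bstop[b]])
    if (length(st) == 1) single[b] <- st
  }
  e_by_id <- bursts$e_raw[match(data$burst_id, bursts$burst_id)]
  groups <- data.frame(state = seq_len(K), n_bursts = 0L,
                       mean_e = NA_real_)
  hists <- vector("list", K)
  for (i in seq_len(K)) {
    sel <- which(single == i)
    groups$n_bursts[i] <- length(sel)
    if (length(sel)) {
      groups$mean_e[i] <- mean(e_by_id[sel], na.rm = TRUE)
      hb <- data.frame(e_raw = e_by_id[sel], flagged = FALSE)
      hists[[i]] <- fret_histogram(hb, n_bins = n_bins)
    }
  }
  list(assignments = single, groups = groups, histograms = hists)
}

#' Burst-wise fluorescence correlation analysis
#'
#' The fourth validation: conformational exchange between states of
#' different FRET efficiency modulates the donor and acceptor count rates,
#' so the photon-pair correlation within bursts decays (autocorrelations)
#' or recovers (donor-acceptor cross-correlation, which is anti-correlated)
#' on the exchange timescale. The estimator counts photon pairs per burst
#' on a logarithmic lag grid, normalizes by the rate expected for
#' uncorrelated Poisson counts given each burst's duration (with the
#' triangular finite-window factor), pools over bursts, and scales the
#' curve to 1 at the largest computed lag. Lags longer than a burst drop
#' that burst from both numerator and denominator.
#'
#' Only donor-excitation photons are used: `"DxD"` and `"AxA"` are the
#' channel autocorrelations, `"DxA"` the cross-correlation.
#'
#' @param data a `photon_set` from [h2mm_data()].
#' @param channel_pair one of `"DxD"`, `"AxA"`, `"DxA"`.
#' @param lag_min,lag_max lag-grid limits in seconds.
#' @param points_per_decade logarithmic grid density.
#' @return An object of class `"correlation_curve"`: data frame with
#'   columns `lag_s` (bin center), `G` (normalized amplitude), `n_pairs`,
#'   `n_bursts` (bursts contributing at that lag).
#' @export
burstwise_fcs <- function(data, channel_pair = c("DxA", "DxD", "AxA"),
                          lag_min = 1e-5, lag_max = 1e-2,
                          points_per_decade = 8) {
  channel_pair <- match.arg(channel_pair)
  if (data$n_bursts < 100) {
    warning("fewer than 100 bursts; correlation estimate will be noisy")
  }
  cp <- data$clock_period
  n_dec <- log10(lag_max / lag_min)
  edges <- lag_min * 10^(seq(0, n_dec, length.out =
                               round(points_per_decade * n_dec) + 1))
  n_lag <- length(edges) - 1
  centers <- sqrt(edges[-1] * edges[-(n_lag + 1)])
  widths <- diff(edges)
  want <- switch(channel_pair,
                 DxD = c(0L, 0L), AxA = c(1L, 1L), DxA = c(0L, 1L))
  pair_counts <- numeric(n_lag)
  expected <- numeric(n_lag)
  nb_at <- integer(n_lag)
  for (b in seq_len(data$n_bursts)) {
    idx <- (data$bstart[b] + 1L):data$bstop[b]
    tt <- data$ticks[idx] * cp
    dur <- tt[length(tt)] - tt[1]
    if (dur <= 0) next
    tx <- tt[data$colors[idx] == want[1]]
    ty <- tt[data$colors[idx] == want[2]]
    if (!length(tx) || !length(ty)) next
    diffs <- as.vector(outer(ty, tx, `-`))
    diffs <- diffs[diffs > 0]
    usable <- which(edges[-1] <= dur)
    if (!length(usable)) next
    if (length(diffs)) {
      h <- findInterval(diffs, edges, rightmost.closed = TRUE)
      h <- h[h >= 1 & h <= n_lag]
      tab <- tabulate(h, nbins = n_lag)
      pair_counts[usable] <- pair_counts[usable] + tab[usable]
    }
    nx <- length(tx); ny <- length(ty)
    same <- want[1] == want[2]
    # expected ordered-pair count for uncorrelated Poisson arrivals in a
    # window of length dur: n_x n_y w (1 - tau/dur) / dur  (triangular
    # overlap); subtract self-pairs for autocorrelation
    npairs <- if (same) nx * (ny - 1) else nx * ny
    exp_b <- npairs * widths[usable] *
      pmax(1 - centers[usable] / dur, 0) / dur
    expected[usable] <- expected[usable] + exp_b
    nb_at[usable] <- nb_at[usable] + 1L
  }
  G <- ifelse(expected > 0, pair_counts / expected, NA_real_)
  # keep lags with adequate burst support: the per-burst count
  # normalization carries a lag-independent covariance bias that the
  # long-lag plateau normalization removes, so the reference must itself
  # be well estimated
  support <- max(30, ceiling(0.1 * data$n_bursts))
  ok <- !is.na(G) & nb_at >= min(support, max(nb_at))
  ref_idx <- utils::tail(which(ok), 3)
  G_ref <- mean(G[ref_idx])
  structure(
    data.frame(lag_s = centers, G = G / G_ref, n_pairs = pair_counts,
               n_bursts = nb_at)[ok, ],
    class = c("correlation_curve", "data.frame")
  )
}

#' Characteristic time of a correlation curve
#'
#' Fits `G(tau) = 1 + A exp(-tau / tau_c)` to a [burstwise_fcs()] curve by
#' nonlinear least squares; for two-state exchange `tau_c = 1 /
#' (k_12 + k_21)`. The amplitude sign distinguishes autocorrelation decays
#' (`A > 0`) from donor-acceptor anti-correlation (`A < 0`).
#'
#' @param curve a `correlation_curve`.
#' @return A list with `tau_c`, `amplitude`, and the `nls` fit object.
#' @export
fcs_relaxation_time <- function(curve) {
  df <- as.data.frame(curve)
  df <- df[is.finite(df$G), ]
  a0 <- df$G[1] - 1
  if (abs(a0) < 1e-6) a0 <- sign(a0 + 1e-12) * 0.01
  fit <- minpack.lm::nlsLM(
    G ~ 1 + A * exp(-lag_s / tau_c), data = df,
    start = list(A = a0, tau_c = stats::median(df$lag_s)),
    lower = c(-2, 1e-7), upper = c(2, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(tau_c = unname(co["tau_c"]), amplitude = unname(co["A"]), fit = fit)
}
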