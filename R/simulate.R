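#' Exact stochastic simulation of the hidden state path
#'
#' Simulates one realization of the continuous-time Markov chain with
#' generator `Q` over `[0, duration]` by the direct (Gillespie) method:
#' holding times are exponential with rate `-Q[i, i]`, jump targets are
#' drawn with probability `k_ij / (-Q[i, i])`, and the path is truncated at
#' `duration`. A state with zero exit rate yields a single-segment path.
#'
#' @param Q rate matrix (s^-1), rows summing to zero.
#' @param duration trajectory length in seconds (> 0).
#' @param start_state initial state index; if `NULL`, drawn from `p0`.
#' @param p0 initial state distribution used when `start_state` is `NULL`;
#'   default stationary.
#' @return A list with `states` (visited states, in order) and `times`
#'   (entry time of each segment in seconds, starting at 0); segment `i`
#'   spans `[times[i], times[i + 1])`, the last ending at `duration`.
#' @export
simulate_state_path <- function(Q, duration, start_state = NULL, p0 = NULL) {
  K <- nrow(Q)
  if (duration <= 0) stop("duration must be positive")
  if (is.null(start_state)) {
    if (is.null(p0)) p0 <- steady_state(Q)
    start_state <- sample.int(K, 1, prob = p0)
  }
  states <- integer(16); times <- numeric(16)
  s <- as.integer(start_state); t <- 0; n <- 0L
  repeat {
    n <- n + 1L
    if (n > length(states)) {
      length(states) <- 2 * length(states)
      length(times) <- 2 * length(times)
    }
    states[n] <- s; times[n] <- t
    exit <- -Q[s, s]
    if (exit <= 0) break
    t <- t + stats::rexp(1, exit)
    if (t >= duration) break
    rates <- Q[s, ]; rates[s] <- 0
    s <- sample.int(K, 1, prob = rates)
  }
  list(states = states[seq_len(n)], times = times[seq_len(n)],
       duration = duration)
}

#' Simulate a burst dataset of photon trajectories
#'
#' Generates `n_bursts` molecule transits from a [ground_truth_model()]:
#' per burst an exponential duration, a hidden Gillespie state path, a
#' Poisson stream of donor-excitation photons colored acceptor with the
#' current state's FRET efficiency, a Poisson stream of acceptor-excitation
#' (all-acceptor) photons, and optional uniform background photons in each
#' channel. Bursts are separated by ten times the mean burst duration, so a
#' burst search on the returned stream recovers them; the returned burst
#' table indexes the stream directly. Photon times are rounded to clock
#' ticks; coincident ticks are pushed apart by one tick to keep inter-photon
#' gaps at least one tick.
#'
#' @param model a [ground_truth_model()].
#' @param n_bursts number of bursts (>= 1).
#' @param seed integer seed; the simulation is a deterministic function of
#'   `(model, n_bursts, seed)`.
#' @return A list with `stream` (a [photon_stream]), `bursts` (a filled
#'   burst table) and `truth` (per-burst hidden paths: `states`, `times`
#'   in seconds from burst start, `duration`, `photon_states` for
#'   donor-excitation photons, plus the `seed`).
#' @export
simulate_dataset <- function(model, n_bursts, seed = 1L) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (n_bursts < 1) stop("n_bursts must be at least 1")
  set.seed(seed)
  cp <- model$clock_period
  gap_s <- 10 * model$burst_duration_mean
  E <- model$efficiencies
  bg <- model$background_rates
  ts_all <- vector("list", n_bursts)
  ch_all <- vector("list", n_bursts)
  sl_all <- vector("list", n_bursts)
  truth <- vector("list", n_bursts)
  t0 <- 0
  for (b in seq_len(n_bursts)) {
    dur <- stats::rexp(1, 1 / model$burst_duration_mean)
    path <- simulate_state_path(model$rate_matrix, dur,
                                p0 = model$initial_distribution)
    n_dex <- stats::rpois(1, model$photon_rate * dur)
    t_dex <- sort(stats::runif(n_dex, 0, dur))
    st <- path$states[findInterval(t_dex, path$times)]
    col <- stats::rbinom(n_dex, 1, E[st])  # 1 = acceptor
    n_aex <- stats::rpois(1, model$aex_photon_rate * dur)
    t_aex <- stats::runif(n_aex, 0, dur)
    if (n_dex + n_aex == 0) {
      # a transit that yields no photons is never detected; condition on at
      # least one donor-excitation photon so every burst is observable
      n_dex <- 1L
      t_dex <- stats::runif(1, 0, dur)
      st <- path$states[findInterval(t_dex, path$times)]
      col <- stats::rbinom(1, 1, E[st])
    }
    t_bgd <- stats::runif(stats::rpois(1, bg[["D"]] * dur), 0, dur)
    t_bga <- stats::runif(stats::rpois(1, bg[["A"]] * dur), 0, dur)
    tt <- c(t_dex, t_aex, t_bgd, t_bga)
    ch <- c(ifelse(col == 1, "A", "D"), rep("A", n_aex),
            rep("D", length(t_bgd)), rep("A", length(t_bga)))
    sl <- c(rep("Dex", n_dex), rep("Aex", n_aex),
            rep("Dex", length(t_bgd)), rep("Dex", length(t_bga)))
    ord <- order(tt)
    ticks <- round((t0 + tt[ord]) / cp)
    # enforce strictly increasing ticks (unit-tick minimum gap)
    if (length(ticks) > 1) ticks <- ticks + cumsum(c(0, diff(ticks) < 1))
    ts_all[[b]] <- ticks
    ch_all[[b]] <- ch[ord]
    sl_all[[b]] <- sl[ord]
    truth[[b]] <- list(states = path$states, times = path$times,
                       duration = dur, photon_states = st,
                       photon_times = t_dex, photon_colors = col)
    t0 <- t0 + dur + gap_s
  }
  counts <- lengths(ts_all)
  stop_idx <- cumsum(counts)
  start_idx <- stop_idx - counts + 1L
  stream <- photon_stream(unlist(ts_all), unlist(ch_all), unlist(sl_all),
                          clock_period = cp,
                          metadata = list(label = model$label, seed = seed))
  keep <- counts > 0
  bursts <- burst_table(start_idx[keep], stop_idx[keep] + 1L)
  bursts <- compute_burst_quantities(stream, bursts)
  list(stream = stream, bursts = bursts,
       truth = list(seed = seed, per_burst = truth[keep],
                    model_label = model$label))
}

#' Simulate an ATP titration series
#'
#' At each ligand concentration `c`, bursts are drawn from the
#' saturated-condition model with probability given by the Hill law
#' `Y(c) = c^n / (K^n + c^n)` and from the apo model otherwise, emulating a
#' concerted two-macrostate partition along the titration. Per-burst
#' macrostate labels are stored in the truth record.
#'
#' @param conc concentrations (any consistent unit; micromolar in the
#'   intended use), >= 0.
#' @param hill_n Hill coefficient of the generating law (> 0).
#' @param hill_k apparent binding constant, same unit as `conc`.
#' @param model_apo,model_sat ground-truth models for the two macrostates.
#' @param n_bursts_per_conc bursts per concentration.
#' @param seed integer seed.
#' @return A named list (one element per concentration, names = `conc`) of
#'   datasets as returned by [simulate_dataset()], each augmented with
#'   `truth$macrostate` (`"apo"`/`"sat"` per burst) and
#'   `truth$mix_fraction`.
#' @export
simulate_titration <- function(conc, hill_n, hill_k, model_apo, model_sat,
                               n_bursts_per_conc, seed = 1L) {
  if (any(conc < 0)) stop("concentrations must be non-negative")
  out <- vector("list", length(conc))
  names(out) <- as.character(conc)
  for (i in seq_along(conc)) {
    c_i <- conc[i]
    y <- if (c_i == 0) 0 else c_i^hill_n / (hill_k^hill_n + c_i^hill_n)
    seed_i <- as.integer((as.numeric(seed) * 997 + i) %% 2147483629)
    set.seed(seed_i)
    lab <- stats::rbinom(n_bursts_per_conc, 1, y)  # 1 = saturated macrostate
    # simulate the two sub-populations separately, then interleave by label
    n_sat <- sum(lab)
    ds_apo <- if (n_sat < n_bursts_per_conc) {
      simulate_dataset(model_apo, n_bursts_per_conc - n_sat,
                       seed = as.integer((2 * as.numeric(seed_i) + 1) %%
                                           2147483629))
    }
    ds_sat <- if (n_sat > 0) {
      simulate_dataset(model_sat, n_sat,
                       seed = as.integer((2 * as.numeric(seed_i) + 2) %%
                                           2147483629))
    }
    out[[i]] <- merge_titration_point(ds_apo, ds_sat, lab, y, c_i)
  }
  out
}

# Interleave the apo-generated and saturated-generated bursts of one
# titration point into a single stream in label order.
merge_titration_point <- function(ds_apo, ds_sat, lab, y, conc) {
  pick <- list(apo = ds_apo, sat = ds_sat)
  n <- length(lab)
  streams_ts <- vector("list", n)
  streams_ch <- vector("list", n)
  streams_sl <- vector("list", n)
  per_burst <- vector("list", n)
  idx <- c(apo = 0L, sat = 0L)
  t0 <- 0
  cp <- if (!is.null(ds_apo)) ds_apo$stream$clock_period else
    ds_sat$stream$clock_period
  for (b in seq_len(n)) {
    which_m <- if (lab[b] == 1) "sat" else "apo"
    idx[which_m] <- idx[which_m] + 1L
    src <- pick[[which_m]]
    k <- idx[[which_m]]
    rng <- src$bursts$start[k]:(src$bursts$stop[k] - 1L)
    tk <- src$stream$timestamps[rng]
    tk <- tk - tk[1]
    streams_ts[[b]] <- tk + round(t0 / cp)
    streams_ch[[b]] <- src$stream$channel[rng]
    streams_sl[[b]] <- src$stream$slot[rng]
    per_burst[[b]] <- src$truth$per_burst[[k]]
    t0 <- t0 + src$truth$per_burst[[k]]$duration + 10e-3
  }
  counts <- lengths(streams_ts)
  stop_idx <- cumsum(counts)
  start_idx <- stop_idx - counts + 1L
  stream <- photon_stream(unlist(streams_ts), unlist(streams_ch),
                          unlist(streams_sl), clock_period = cp,
                          metadata = list(conc = conc))
  bursts <- burst_table(start_idx, stop_idx + 1L)
  bursts <- compute_burst_quantities(stream, bursts)
  list(stream = stream, bursts = bursts,
       truth = list(per_burst = per_burst,
                    macrostate = ifelse(lab == 1, "sat", "apo"),
                    mix_fraction = y, conc = conc))
}
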