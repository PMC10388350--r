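#' Assemble donor-excitation photon records for HMM fitting
#'
#' Extracts, per burst, the donor-excitation photons (the only ones carrying
#' FRET information; acceptor-excitation photons serve stoichiometry only)
#' as color codes (0 = donor, 1 = acceptor channel) and arrival ticks.
#' Bursts without donor-excitation photons are dropped.
#'
#' @param stream a [photon_stream].
#' @param bursts a burst table ([burst_search()] /
#'   [compute_burst_quantities()]).
#' @return An object of class `"photon_set"`: concatenated `colors` and
#'   `ticks` with 0-based half-open burst index ranges `bstart`/`bstop`,
#'   the originating `burst_id`s and the `clock_period`.
#' @export
h2mm_data <- function(stream, bursts) {
  stopifnot(inherits(stream, "photon_stream"))
  colors_all <- vector("list", nrow(bursts))
  ticks_all <- vector("list", nrow(bursts))
  keep <- logical(nrow(bursts))
  for (b in seq_len(nrow(bursts))) {
    idx <- bursts$start[b]:(bursts$stop[b] - 1L)
    dex <- idx[stream$slot[idx] == "Dex"]
    if (!length(dex)) next
    keep[b] <- TRUE
    colors_all[[b]] <- as.integer(stream$channel[dex] == "A")
    ticks_all[[b]] <- stream$timestamps[dex]
  }
  counts <- lengths(colors_all)[keep]
  stopn <- cumsum(counts)
  structure(
    list(colors = unlist(colors_all[keep]),
         ticks = unlist(ticks_all[keep]),
         bstart = c(0, stopn[-length(stopn)]),
         bstop = stopn,
         burst_id = bursts$burst_id[keep],
         clock_period = stream$clock_period,
         n_bursts = sum(keep)),
    class = "photon_set"
  )
}

#' @export
print.photon_set <- function(x, ...) {
  cat("<photon_set>", x$n_bursts, "bursts,", length(x$colors),
      "donor-excitation photons\n")
  invisible(x)
}

# Inter-photon tick gaps aligned with the photon vector; the entry at each
# burst start is unused by the recursions and set to 0.
photon_gaps <- function(data) {
  gaps <- c(0, diff(data$ticks))
  gaps[data$bstart + 1] <- 0
  if (any(gaps[-(data$bstart + 1)] < 1)) {
    stop("inter-photon gaps must be at least one clock tick")
  }
  gaps
}

subset_photon_set <- function(data, which_bursts) {
  idx_list <- lapply(which_bursts, function(b) {
    seq.int(data$bstart[b] + 1L, data$bstop[b])
  })
  counts <- lengths(idx_list)
  stopn <- cumsum(counts)
  idx <- unlist(idx_list)
  structure(
    list(colors = data$colors[idx], ticks = data$ticks[idx],
         bstart = c(0, stopn[-length(stopn)]), bstop = stopn,
         burst_id = data$burst_id[which_bursts],
         clock_period = data$clock_period,
         n_bursts = length(which_bursts)),
    class = "photon_set"
  )
}

#' Forward-backward analysis of photon trajectories
#'
#' Runs the scaled forward-backward recursions of the photon-by-photon HMM
#' over each burst: propagation between photons uses `T^dt` over the integer
#' tick gap (via eigendecomposition of the per-tick matrix), emissions apply
#' at photon arrivals. Returns per-burst log-likelihoods, per-photon
#' posterior state probabilities and the expected per-tick transition-count
#' matrix accumulated over all gaps (including the unobserved ticks inside
#' them).
#'
#' @param model an [h2mm_model()].
#' @param data a `photon_set` from [h2mm_data()], or a single-burst list
#'   with elements `colors` (0/1 or `"D"`/`"A"`) and `gaps` (ticks, first
#'   entry ignored).
#' @return A list with `loglik` (per burst), `posteriors` (photons x K) and
#'   `expected_transitions` (K x K).
#' @export
forward_backward <- function(model, data) {
  d <- as_fit_arrays(model, data)
  out <- h2mm_fwdbwd_cpp(d$colors, d$gaps, d$bstart, d$bstop,
                         d$T, emission_matrix(model),
                         model$initial_distribution, TRUE)
  out$loglik <- as.numeric(out$loglik)
  out
}

#' Per-burst log-likelihood under a model
#'
#' Forward pass only; equals the log-likelihood component of
#' [forward_backward()]. This is the quantity the macrostate likelihood
#' test consumes.
#'
#' @inheritParams forward_backward
#' @return Numeric vector, one log-likelihood per burst.
#' @export
burst_loglik <- function(model, data) {
  d <- as_fit_arrays(model, data)
  as.numeric(h2mm_fwdbwd_cpp(d$colors, d$gaps, d$bstart, d$bstop,
                             d$T, emission_matrix(model),
                             model$initial_distribution, FALSE)$loglik)
}

#' Most likely state sequence per photon trajectory
#'
#' Viterbi decoding with `T^dt` inter-photon propagation: returns, per
#' photon, the state of the jointly most probable photon-time state
#' sequence, plus a segment table. Segment boundaries are placed at the
#' midpoint of the inter-photon gap across which the decoded state changes;
#' the first and last segments of each burst are marked as edge (censored)
#' segments.
#'
#' @inheritParams forward_backward
#' @return A list with `states` (1-based state per photon), `path_loglik`
#'   (per burst) and `segments` (data frame: `burst`, `state`, `start_s`,
#'   `end_s`, `duration_s`, `n_photons`, `edge`).
#' @export
viterbi <- function(model, data) {
  d <- as_fit_arrays(model, data)
  out <- h2mm_viterbi_cpp(d$colors, d$gaps, d$bstart, d$bstop,
                          d$T, emission_matrix(model),
                          model$initial_distribution)
  states <- as.integer(out$path) + 1L
  out$path_loglik <- as.numeric(out$path_loglik)
  segments <- NULL
  if (!is.null(d$ticks)) {
    segments <- viterbi_segments(states, d, model$clock_period)
  }
  list(states = states, path_loglik = out$path_loglik, segments = segments)
}

viterbi_segments <- function(states, d, clock_period) {
  res <- vector("list", length(d$bstart))
  for (b in seq_along(d$bstart)) {
    idx <- (d$bstart[b] + 1L):d$bstop[b]
    st <- states[idx]
    tk <- d$ticks[idx]
    r <- rle(st)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    # boundary times: midpoints of the gap between adjacent segments
    n_seg <- length(r$values)
    bound <- numeric(n_seg + 1)
    bound[1] <- tk[1]
    bound[n_seg + 1] <- tk[length(tk)]
    if (n_seg > 1) {
      for (s in seq_len(n_seg - 1)) {
        bound[s + 1] <- (tk[ends_i[s]] + tk[starts_i[s + 1]]) / 2
      }
    }
    res[[b]] <- data.frame(
      burst = b, state = r$values,
      start_s = bound[-(n_seg + 1)] * clock_period,
      end_s = bound[-1] * clock_period,
      n_photons = r$lengths,
      edge = seq_len(n_seg) %in% c(1L, n_seg)
    )
  }
  out <- do.call(rbind, res)
  out$duration_s <- out$end_s - out$start_s
  out
}

# Normalize inputs for the C++ kernels: accepts a photon_set or a
# single-burst list(colors, gaps).
as_fit_arrays <- function(model, data) {
  T <- tick_transition(model$rate_matrix, model$clock_period)
  if (inherits(data, "photon_set")) {
    list(colors = as.integer(data$colors), gaps = photon_gaps(data),
         bstart = as.integer(data$bstart), bstop = as.integer(data$bstop),
         ticks = data$ticks, T = T)
  } else {
    colors <- data$colors
    if (is.character(colors)) colors <- as.integer(colors == "A")
    n <- length(colors)
    gaps <- data$gaps
    if (is.null(gaps)) gaps <- rep(1, n)
    gaps[1] <- 0
    list(colors = as.integer(colors), gaps = as.numeric(gaps),
         bstart = 0L, bstop = as.integer(n), ticks = data$ticks, T = T)
  }
}

#' Maximum-likelihood fit of a photon-by-photon HMM
#'
#' Baum-Welch expectation-maximization adapted to photon records with
#' irregular inter-photon gaps: expected transition counts are accumulated
#' through the `T^dt` factorization over every tick, observed or not, so
#' the per-tick transition matrix (equivalently the rate matrix) is
#' estimated on its natural time base. The fit is restarted from several
#' jittered initializations; each restart runs a bounded screening phase
#' and the best continues to convergence (log-likelihood change per photon
#' below `tol`, or `max_iter`).
#'
#' States in the returned model are sorted by decreasing FRET efficiency.
#'
#' @param data a `photon_set` from [h2mm_data()].
#' @param K number of hidden states.
#' @param init optional [h2mm_model()] used as the starting point of the
#'   first restart; by default efficiencies start on a uniform grid between
#'   the 5th and 95th percentiles of per-burst acceptor fractions and all
#'   exchange rates at 1000 s^-1.
#' @param restarts number of jittered restarts.
#' @param tol convergence threshold on the log-likelihood change per photon.
#' @param max_iter maximum EM iterations for the polishing phase.
#' @param screen_iter EM iterations allotted to each restart in the
#'   screening phase.
#' @param seed integer seed controlling the restart jitter.
#' @return An object of class `"h2mm_fit"`: `model` (fitted, canonical
#'   state order), `loglik_trace`, `n_iterations`, `converged`, `restarts`
#'   (screening log-likelihoods), `degenerate` (TRUE when two fitted
#'   efficiencies nearly coincide), `n_photons`.
#' @export
em_fit <- function(data, K, init = NULL, restarts = 8, tol = 1e-8,
                   max_iter = 200, screen_iter = 30, seed = 1L) {
  fit_core(list(data), K, init = init, restarts = restarts, tol = tol,
           max_iter = max_iter, screen_iter = screen_iter, seed = seed)
}

#' Global fit with shared FRET efficiencies across conditions
#'
#' Fits one photon-by-photon HMM per dataset with a single shared emission
#' matrix: the M-step pools the emission sufficient statistics over all
#' datasets while transition matrices and initial distributions stay
#' per-dataset. This is the multi-condition analysis that ties the
#' microstate efficiencies together across solution conditions.
#'
#' @param datasets named list of `photon_set` objects (>= 2).
#' @inheritParams em_fit
#' @return An object of class `"h2mm_fit"` whose `models` field holds one
#'   fitted [h2mm_model()] per dataset (shared efficiencies, canonical
#'   order) and `model` the first of them.
#' @export
global_fit <- function(datasets, K, init = NULL, restarts = 8, tol = 1e-8,
                       max_iter = 200, screen_iter = 30, seed = 1L) {
  if (length(datasets) < 2) stop("global_fit needs at least two datasets")
  fit_core(datasets, K, init = init, restarts = restarts, tol = tol,
           max_iter = max_iter, screen_iter = screen_iter, seed = seed)
}

fit_core <- function(datasets, K, init, restarts, tol, max_iter,
                     screen_iter, seed) {
  nd <- length(datasets)
  cp <- datasets[[1]]$clock_period
  colors <- unlist(lapply(datasets, `[[`, "colors"))
  n_photons <- length(colors)
  gaps <- unlist(lapply(datasets, photon_gaps))
  counts <- vapply(datasets, function(d) length(d$colors), 0L)
  offs <- cumsum(c(0L, counts[-nd]))
  bstart <- unlist(mapply(function(d, o) d$bstart + o, datasets, offs,
                          SIMPLIFY = FALSE))
  bstop <- unlist(mapply(function(d, o) d$bstop + o, datasets, offs,
                         SIMPLIFY = FALSE))
  dataset_id <- rep(seq_len(nd) - 1L,
                    vapply(datasets, `[[`, 0L, "n_bursts"))

  burst_e <- burst_acceptor_fractions(datasets)
  inits <- make_inits(K, burst_e, cp, init, restarts, seed, nd)

  run <- function(ini, iters) {
    h2mm_em_cpp(as.integer(colors), as.numeric(gaps),
                as.integer(bstart), as.integer(bstop),
                as.integer(dataset_id), nd,
                ini$T, ini$B, ini$p0, iters, tol)
  }
  screen <- lapply(inits, run, iters = screen_iter)
  lls <- vapply(screen, function(r) {
    r$loglik_trace[length(r$loglik_trace)]
  }, 0)
  best_i <- which.max(lls)
  best <- screen[[best_i]]
  if (!best$converged) {
    cont <- list(T = best$T, B = best$B, p0 = best$p0)
    polished <- run(cont, max_iter)
    trace <- c(best$loglik_trace,
               polished$loglik_trace[-1])
    best <- polished
    best$loglik_trace <- trace
  }
  package_fit(best, datasets, cp, lls, n_photons, best_i)
}

burst_acceptor_fractions <- function(datasets) {
  unlist(lapply(datasets, function(d) {
    vapply(seq_len(d$n_bursts), function(b) {
      idx <- (d$bstart[b] + 1L):d$bstop[b]
      mean(d$colors[idx])
    }, 0)
  }))
}

make_inits <- function(K, burst_e, cp, init, restarts, seed, nd = 1) {
  set.seed(seed)
  base_rate <- 1000
  inits <- vector("list", restarts)
  qs <- stats::quantile(burst_e, c(0.05, 0.95), names = FALSE)
  if (diff(qs) < 0.1) qs <- c(max(qs[1] - 0.1, 0.01), min(qs[2] + 0.1, 0.99))
  e_grid <- seq(qs[1], qs[2], length.out = K)
  wide_grid <- seq(0.1, 0.9, length.out = K)
  for (r in seq_len(restarts)) {
    if (r == 1 && !is.null(init)) {
      E <- init$efficiencies
      Q <- init$rate_matrix
    } else {
      # two deterministic starts (data-driven percentile grid and a fixed
      # wide grid, which rescues conditions whose burst-E distribution is
      # concentrated away from sparsely populated states), then jitters
      # alternating around both
      E <- if (r %% 2 == 1) e_grid else wide_grid
      rate <- base_rate
      if (r > 2) {
        E <- pmin(pmax(E + stats::rnorm(K, 0, 0.05), 0.02), 0.98)
        rate <- base_rate * exp(stats::rnorm(1, 0, 0.5))
      }
      Q <- matrix(rate, K, K)
      diag(Q) <- 0
      if (r > 2) {
        Q[row(Q) != col(Q)] <- Q[row(Q) != col(Q)] *
          exp(stats::rnorm(K * (K - 1), 0, 0.3))
      }
      diag(Q) <- -rowSums(Q)
    }
    T0 <- tick_transition(Q, cp)
    inits[[r]] <- list(
      T = rep(list(T0), nd),
      B = cbind(1 - E, E),
      p0 = rep(list(rep(1 / K, K)), nd)
    )
  }
  inits
}

package_fit <- function(res, datasets, cp, screen_lls, n_photons, best_i) {
  nd <- length(datasets)
  B <- res$B
  E <- B[, 2]
  ord <- order(E, decreasing = TRUE)
  models <- vector("list", nd)
  for (d in seq_len(nd)) {
    T_d <- res$T[[d]][ord, ord, drop = FALSE]
    p0_d <- res$p0[[d]][ord]
    Q_d <- rate_from_tick(T_d, cp)
    models[[d]] <- h2mm_model(Q_d, E[ord], p0_d, cp)
  }
  names(models) <- names(datasets)
  E_sorted <- E[ord]
  degenerate <- any(diff(E_sorted) > -0.005)
  structure(
    list(model = models[[1]], models = models,
         loglik_trace = res$loglik_trace,
         n_iterations = res$n_iterations,
         converged = res$converged,
         restart_logliks = screen_lls, best_restart = best_i,
         degenerate = degenerate, n_photons = n_photons),
    class = "h2mm_fit"
  )
}

#' @export
print.h2mm_fit <- function(x, ...) {
  cat("<h2mm_fit> K =", x$model$n_states, ",", length(x$models),
      "dataset(s),", x$n_photons, "photons\n")
  cat("  loglik",
      format(x$loglik_trace[length(x$loglik_trace)], digits = 10),
      "after", x$n_iterations, "iterations; converged:",
      x$converged, "\n")
  cat("  E:", paste(sprintf("%.3f", x$model$efficiencies),
                    collapse = ", "), "\n")
  if (x$degenerate) cat("  note: nearly degenerate states\n")
  invisible(x)
}

#' Model-size comparison report
#'
#' Fits the photon-by-photon HMM for each candidate state count and reports
#' the maximized log-likelihood, parameter count and BIC (`-2 loglik +
#' n_par log(n_photons)`). No automatic selection is performed; the table is
#' for inspection.
#'
#' @param data a `photon_set`.
#' @param K_values candidate state counts.
#' @param ... passed to [em_fit()].
#' @return Data frame with columns `K`, `loglik`, `n_par`, `bic`,
#'   `converged`.
#' @export
model_selection_report <- function(data, K_values = 2:5, ...) {
  rows <- lapply(K_values, function(K) {
    fit <- em_fit(data, K, ...)
    n_par <- K * (K - 1) + K + (K - 1)  # rates + efficiencies + p0
    ll <- fit$loglik_trace[length(fit$loglik_trace)]
    data.frame(K = K, loglik = ll, n_par = n_par,
               bic = -2 * ll + n_par * log(fit$n_photons),
               converged = fit$converged)
  })
  do.call(rbind, rows)
}
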