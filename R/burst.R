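#' Detection-correction coefficients for FRET efficiency
#'
#' Holds the standard alternating-excitation correction coefficients:
#' donor leakage into the acceptor channel (`leakage`), direct excitation of
#' the acceptor by the donor-excitation pulse (`direct_excitation`), and the
#' donor/acceptor detection-efficiency ratio (`gamma`). The identity set
#' (0, 0, 1) leaves the proximity ratio unchanged.
#'
#' @param leakage fraction of donor signal detected in the acceptor channel
#'   (>= 0).
#' @param direct_excitation fraction of acceptor-excitation signal leaking
#'   into donor-excitation acceptor counts (>= 0).
#' @param gamma detection-efficiency ratio (> 0).
#' @return An object of class `"correction_set"`.
#' @export
correction_set <- function(leakage = 0, direct_excitation = 0, gamma = 1) {
  if (leakage < 0 || direct_excitation < 0) {
    stop("leakage and direct_excitation must be non-negative")
  }
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(leakage = leakage, direct_excitation = direct_excitation,
                 gamma = gamma), class = "correction_set")
}

#' All-photon sliding-window burst search
#'
#' Identifies molecule transits ("bursts") in a photon stream by the
#' community-standard all-photon sliding-window criterion: a photon belongs
#' to a burst region when it lies in a window of `window_m` consecutive
#' photons whose local rate, `(window_m - 1)` photons per window time span,
#' is at least `rate_threshold`. Overlapping qualifying windows are merged
#' maximally, and runs with fewer than `min_size` photons are discarded.
#'
#' @param stream a [photon_stream].
#' @param window_m number of consecutive photons per test window (>= 2).
#' @param rate_threshold minimum local photon rate in photons/s (> 0).
#' @param min_size minimum number of photons per burst (>= 1).
#' @return A data frame with one row per burst and columns `burst_id`,
#'   `start`, `stop` (half-open photon-index range, 1-based: photons
#'   `start .. stop - 1`), plus the columns filled by
#'   [compute_burst_quantities()] set to `NA`.
#' @export
burst_search <- function(stream, window_m = 10, rate_threshold = 5e4,
                         min_size = 30) {
  stopifnot(inherits(stream, "photon_stream"))
  if (window_m < 2) stop("window_m must be at least 2")
  if (rate_threshold <= 0 || min_size < 1) {
    stop("rate_threshold and min_size must be positive")
  }
  n <- length(stream$timestamps)
  empty <- burst_table(integer(0), integer(0))
  if (n < max(window_m, min_size)) return(empty)
  t <- stream$timestamps
  max_span_ticks <- (window_m - 1) / rate_threshold / stream$clock_period
  span <- t[window_m:n] - t[1:(n - window_m + 1)]
  ok_start <- which(span <= max_span_ticks)
  if (!length(ok_start)) return(empty)
  in_burst <- logical(n)
  for (i in ok_start) in_burst[i:(i + window_m - 1)] <- TRUE
  # split runs across inter-photon gaps no qualifying window could span
  gap_break <- c(FALSE, diff(t) > max_span_ticks)
  run_id <- cumsum(c(TRUE, diff(in_burst) != 0) | gap_break)
  r <- rle(run_id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- in_burst[starts] & r$lengths >= min_size
  burst_table(starts[keep], ends[keep] + 1L)
}

burst_table <- function(start, stop) {
  n <- length(start)
  data.frame(
    burst_id = seq_len(n), start = as.integer(start),
    stop = as.integer(stop),
    n_dd = rep(NA_integer_, n), n_da = rep(NA_integer_, n),
    n_aa = rep(NA_integer_, n),
    duration_s = rep(NA_real_, n), e_raw = rep(NA_real_, n),
    s_raw = rep(NA_real_, n), e_corr = rep(NA_real_, n),
    flagged = logical(n)
  )
}

#' Per-burst photon counts, FRET efficiency and stoichiometry
#'
#' Fills a burst table with per-channel photon counts and the derived
#' quantities: the proximity ratio `e_raw = n_da / (n_dd + n_da)`, the PIE
#' stoichiometry `s_raw = (n_dd + n_da) / (n_dd + n_da + n_aa)`, and the
#' corrected efficiency
#' `e_corr = (n_da - l n_dd - d n_aa) / (gamma n_dd + n_da - l n_dd - d n_aa)`.
#' Only donor-excitation photons enter `e_raw`; acceptor-excitation photons
#' are used for `s_raw` only. Bursts without donor-excitation photons have
#' undefined efficiency and are flagged for downstream exclusion.
#'
#' @param stream a [photon_stream].
#' @param bursts a burst table from [burst_search()] (or with valid
#'   `start`/`stop` columns).
#' @param corrections a [correction_set()]; the default applies no
#'   correction, so `e_corr == e_raw`.
#' @return The burst table with `n_dd`, `n_da`, `n_aa`, `duration_s`,
#'   `e_raw`, `s_raw`, `e_corr` and `flagged` filled.
#' @export
compute_burst_quantities <- function(stream, bursts,
                                     corrections = correction_set()) {
  stopifnot(inherits(stream, "photon_stream"))
  if (any(bursts$stop <= bursts$start)) {
    stop("invalid burst range: stop must exceed start")
  }
  if (nrow(bursts) &&
      (min(bursts$start) < 1 || max(bursts$stop) > length(stream) + 1)) {
    stop("burst range outside stream")
  }
  l <- corrections$leakage
  d <- corrections$direct_excitation
  g <- corrections$gamma
  for (b in seq_len(nrow(bursts))) {
    idx <- bursts$start[b]:(bursts$stop[b] - 1L)
    ch <- stream$channel[idx]
    sl <- stream$slot[idx]
    n_dd <- sum(sl == "Dex" & ch == "D")
    n_da <- sum(sl == "Dex" & ch == "A")
    n_aa <- sum(sl == "Aex" & ch == "A")
    bursts$n_dd[b] <- n_dd
    bursts$n_da[b] <- n_da
    bursts$n_aa[b] <- n_aa
    bursts$duration_s[b] <-
      (stream$timestamps[max(idx)] - stream$timestamps[min(idx)]) *
      stream$clock_period
    if (n_dd + n_da == 0) {
      bursts$flagged[b] <- TRUE
      next
    }
    bursts$e_raw[b] <- n_da / (n_dd + n_da)
    bursts$s_raw[b] <- (n_dd + n_da) / (n_dd + n_da + n_aa)
    num <- n_da - l * n_dd - d * n_aa
    bursts$e_corr[b] <- num / (g * n_dd + num)
  }
  bursts
}

#' Select bursts by PIE stoichiometry
#'
#' Keeps bursts with `s_min <= s_raw <= s_max`, the standard selection of
#' doubly labeled molecules (donor-only transits pile up at S ~ 1,
#' acceptor-only at S ~ 0). Order is preserved; flagged bursts are dropped.
#'
#' @param bursts a filled burst table.
#' @param s_min,s_max stoichiometry window, `0 <= s_min < s_max <= 1`.
#' @return The filtered burst table.
#' @export
stoichiometry_filter <- function(bursts, s_min = 0.3, s_max = 0.8) {
  if (!(s_min >= 0 && s_min < s_max && s_max <= 1)) {
    stop("require 0 <= s_min < s_max <= 1")
  }
  keep <- !bursts$flagged & !is.na(bursts$s_raw) &
    bursts$s_raw >= s_min & bursts$s_raw <= s_max
  bursts[keep, , drop = FALSE]
}

#' Burst-averaged FRET efficiency histogram
#'
#' Histograms per-burst FRET efficiencies on `n_bins` equal bins spanning
#' \[0, 1\]. Flagged bursts (no donor-excitation photons) are excluded.
#'
#' @param bursts a filled burst table.
#' @param n_bins number of bins (>= 2).
#' @param use_corrected use `e_corr` instead of the proximity ratio `e_raw`.
#' @return A data frame with columns `bin_left`, `bin_right`, `bin_center`,
#'   `count`, `density` (counts normalized to unit integral over \[0, 1\]).
#' @export
fret_histogram <- function(bursts, n_bins = 40, use_corrected = FALSE) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  e <- if (use_corrected) bursts$e_corr else bursts$e_raw
  e <- e[!bursts$flagged & !is.na(e)]
  edges <- seq(0, 1, length.out = n_bins + 1)
  # clamp corrected values that fall marginally outside [0, 1]
  e <- pmin(pmax(e, 0), 1)
  idx <- pmin(findInterval(e, edges, rightmost.closed = TRUE), n_bins)
  count <- tabulate(idx, nbins = n_bins)
  width <- diff(edges)
  data.frame(
    bin_left = edges[-(n_bins + 1)], bin_right = edges[-1],
    bin_center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    count = count,
    density = if (sum(count)) count / sum(count) / width else rep(0, n_bins)
  )
}

#' Export a burst table as CSV
#'
#' @param bursts a filled burst table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_burst_table <- function(bursts, path) {
  cols <- c("burst_id", "start", "stop", "n_dd", "n_da", "n_aa",
            "duration_s", "e_raw", "s_raw", "e_corr")
  utils::write.csv(bursts[, cols], path, row.names = FALSE)
  invisible(path)
}
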