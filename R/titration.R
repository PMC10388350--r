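#' Per-burst macrostate likelihood score
#'
#' The likelihood test that assigns each measured molecule transit to one of
#' two macrostate models (apo vs ligand-saturated): with equal priors, the
#' posterior probability of the saturated macrostate is
#' `L_sat / (L_apo + L_sat)`, computed stably from the per-burst
#' log-likelihoods of [burst_loglik()]. Both models must share their
#' emission efficiencies (a global fit), so the score reflects kinetics and
#' populations, not emission differences.
#'
#' @param data a `photon_set` of bursts to score.
#' @param model_apo,model_sat the two macrostate models ([h2mm_model()]).
#' @return Numeric vector of scores in \[0, 1\], one per burst (`NA` for
#'   bursts whose likelihood vanishes under both models).
#' @export
macrostate_score <- function(data, model_apo, model_sat) {
  ll_apo <- burst_loglik(model_apo, data)
  ll_sat <- burst_loglik(model_sat, data)
  score <- stats::plogis(ll_sat - ll_apo)
  score[!is.finite(ll_apo) & !is.finite(ll_sat)] <- NA_real_
  score
}

#' Endpoint-calibrated saturation curve
#'
#' Builds the titration response from per-burst macrostate scores: at each
#' concentration the mean score is computed, then the curve is linearly
#' rescaled so that the zero-concentration point maps to 0 and the
#' saturating point to 1. Under the two-macrostate mixture model the scaled
#' mean is an unbiased estimator of the per-burst fraction in the saturated
#' macrostate. Standard errors come from a burst-level bootstrap.
#'
#' @param datasets named list mapping concentration to `photon_set` (names
#'   coercible to numeric concentrations), or a list of per-concentration
#'   score vectors via `scores`.
#' @param model_apo,model_sat macrostate models passed to
#'   [macrostate_score()].
#' @param scores optional list of precomputed per-burst score vectors (same
#'   names as concentrations); when given, `datasets` and the models are
#'   ignored.
#' @param conc numeric concentrations; default parsed from names.
#' @param n_boot bootstrap resamples for the standard errors.
#' @param seed seed for the bootstrap.
#' @return A data frame of class `"saturation_curve"` with columns
#'   `conc_uM`, `score` (scaled), `se`, `n_bursts`, `raw_score`.
#' @export
saturation_curve <- function(datasets = NULL, model_apo = NULL,
                             model_sat = NULL, scores = NULL, conc = NULL,
                             n_boot = 1000, seed = 1L) {
  if (is.null(scores)) {
    scores <- lapply(datasets, macrostate_score, model_apo = model_apo,
                     model_sat = model_sat)
  }
  if (is.null(conc)) conc <- as.numeric(names(scores))
  if (anyNA(conc)) stop("concentrations could not be parsed from names")
  if (is.unsorted(conc)) {
    ord <- order(conc)
    conc <- conc[ord]
    scores <- scores[ord]
  }
  if (conc[1] != 0) {
    stop("calibration requires a zero-concentration endpoint dataset ",
         "(or pass explicit calibration scores)")
  }
  scores <- lapply(scores, function(s) s[!is.na(s)])
  raw <- vapply(scores, mean, 0)
  m0 <- raw[1]
  m1 <- raw[length(raw)]
  if (m1 <= m0) stop("saturating endpoint does not exceed the zero endpoint")
  set.seed(seed)
  se_raw <- vapply(scores, function(s) {
    n <- length(s)
    bm <- vapply(seq_len(n_boot), function(i) {
      mean(s[sample.int(n, n, replace = TRUE)])
    }, 0)
    stats::sd(bm)
  }, 0)
  structure(
    data.frame(conc_uM = conc,
               score = (raw - m0) / (m1 - m0),
               se = se_raw / (m1 - m0),
               n_bursts = vapply(scores, length, 0L),
               raw_score = raw),
    class = c("saturation_curve", "data.frame")
  )
}

#' Hill-equation fit of a saturation curve
#'
#' Weighted least-squares fit of
#' `Y(c) = Y0 + A * c^n / (K^n + c^n)`
#' with weights `1 / se^2`, multistarted over Hill coefficients
#' `n in {1, 2, 3, 4}` (best residual sum wins). The Hill coefficient `n`
#' measures cooperativity; `K` is the apparent binding constant in the
#' concentration unit of the input.
#'
#' @param points a `saturation_curve` (or data frame with `conc_uM`,
#'   `score` and optionally `se`).
#' @param weights optional explicit weights; default `1 / se^2` when `se`
#'   is available and positive, else unweighted.
#' @return An object of class `"hill_fit"`: `n_hill`, `k_app`, `amplitude`,
#'   `baseline`, `covariance`, `residuals`, `fit` (the underlying `nls`
#'   object).
#' @export
hill_fit <- function(points, weights = NULL) {
  df <- as.data.frame(points)
  if (nrow(df) < 4) stop("need at least 4 concentrations")
  if (length(unique(df$conc_uM)) < 4) stop("need at least 4 distinct concentrations")
  rng <- range(df$score)
  if (diff(rng) < 0.2) {
    warning("saturation range is narrow; Hill parameters will be poorly ",
            "constrained")
  }
  if (is.null(weights)) {
    if (!is.null(df$se) && all(is.finite(df$se)) && all(df$se > 0)) {
      weights <- 1 / df$se^2
    } else {
      weights <- rep(1, nrow(df))
    }
  }
  # half-saturation guess by linear interpolation
  k0 <- tryCatch({
    half <- (max(df$score) + min(df$score)) / 2
    stats::approx(df$score, df$conc_uM, xout = half, ties = mean)$y
  }, error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(df$conc_uM[df$conc_uM > 0])
  best <- NULL
  for (n0 in 1:4) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        score ~ y0 + a * ifelse(conc_uM > 0,
                                conc_uM^n / (k^n + conc_uM^n), 0),
        data = df, weights = weights,
        start = list(y0 = min(df$score), a = diff(rng), k = k0, n = n0),
        lower = c(-0.5, 1e-3, 1e-6, 0.1), upper = c(1, 2, 1e6, 10),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(weights * stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  co <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  structure(
    list(n_hill = unname(co["n"]), k_app = unname(co["k"]),
         amplitude = unname(co["a"]), baseline = unname(co["y0"]),
         covariance = vc, residuals = stats::resid(best$fit),
         fit = best$fit),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  se <- if (!is.null(x$covariance)) sqrt(diag(x$covariance)) else NULL
  cat("<hill_fit>\n")
  cat(sprintf("  n_H   = %.3f%s\n", x$n_hill,
              if (!is.null(se)) sprintf(" +- %.3f", se["n"]) else ""))
  cat(sprintf("  K_app = %.3f%s\n", x$k_app,
              if (!is.null(se)) sprintf(" +- %.3f", se["k"]) else ""))
  cat(sprintf("  A = %.3f, Y0 = %.3f\n", x$amplitude, x$baseline))
  invisible(x)
}

#' Hill saturation law
#'
#' `Y(c) = c^n / (K^n + c^n)`.
#'
#' @param conc concentrations (>= 0).
#' @param n Hill coefficient.
#' @param k apparent binding constant.
#' @return Fractional saturation in \[0, 1\].
#' @export
hill_law <- function(conc, n, k) {
  ifelse(conc > 0, conc^n / (k^n + conc^n), 0)
}
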