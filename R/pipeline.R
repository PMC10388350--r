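#' Derive per-stage child seeds from one root seed
#'
#' Every stage of the reproduction suite draws its randomness from a child
#' seed derived deterministically from a single root seed, so stages are
#' independently reproducible. Children stay below 2^31.
#'
#' @param seed root integer seed.
#' @param stage stage index (1-based).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 8 + stage) %% .Machine$integer.max)
}

#' Simulate a macrostate condition and return fit-ready data
#'
#' Convenience wrapper: builds the named macrostate fixture, simulates
#' `n_bursts` photon trajectories and assembles the donor-excitation
#' photon records.
#'
#' @param condition fixture name (see [make_macrostate_fixture()]).
#' @param n_bursts bursts to simulate.
#' @param seed integer seed.
#' @param ... passed to [make_macrostate_fixture()].
#' @return A list with `model` (ground truth), `dataset`
#'   ([simulate_dataset()] output) and `data` (a `photon_set`).
#' @export
simulate_condition <- function(condition, n_bursts, seed, ...) {
  model <- make_macrostate_fixture(condition, ...)
  ds <- simulate_dataset(model, n_bursts, seed = seed)
  list(model = model, dataset = ds,
       data = h2mm_data(ds$stream, ds$bursts))
}

#' Global-fit recovery run over several conditions
#'
#' Simulates the named macrostate fixtures, runs the shared-efficiency
#' global fit, and summarizes the recovered efficiencies and per-condition
#' stationary populations — the synthetic reproduction of the
#' multi-condition analysis.
#'
#' @param conditions fixture names.
#' @param n_bursts bursts per condition.
#' @param seed root seed; condition `i` simulates under child seed
#'   `stage_seed(seed, i)` and the fit jitter under `stage_seed(seed, 0)`.
#' @param K states to fit.
#' @param restarts EM restarts.
#' @param ... passed to [global_fit()].
#' @return A list with `fit`, `efficiencies` (sorted, decreasing),
#'   `populations` (condition x state matrix from the fitted rate
#'   matrices), `truth` (the fixtures) and `datasets`.
#' @export
run_global_recovery <- function(conditions = c("apo", "atp"),
                                n_bursts = 5000, seed = 1L, K = 4,
                                restarts = 8, ...) {
  sims <- lapply(seq_along(conditions), function(i) {
    simulate_condition(conditions[i], n_bursts, stage_seed(seed, i))
  })
  names(sims) <- conditions
  datasets <- lapply(sims, `[[`, "data")
  fit <- global_fit(datasets, K = K, restarts = restarts,
                    seed = stage_seed(seed, 0), ...)
  pops <- t(vapply(fit$models, function(m) steady_state(m$rate_matrix),
                   numeric(K)))
  rownames(pops) <- conditions
  list(fit = fit, efficiencies = fit$model$efficiencies,
       populations = pops,
       truth = lapply(sims, `[[`, "model"),
       datasets = datasets)
}

#' Single-condition population recovery run
#'
#' Simulates one macrostate fixture, fits a photon-by-photon HMM, and
#' returns the stationary populations of the fitted rate matrix (states in
#' decreasing-efficiency order).
#'
#' @param condition fixture name.
#' @param n_bursts bursts to simulate.
#' @param seed integer seed (simulation uses `stage_seed(seed, 1)`, fit
#'   jitter `stage_seed(seed, 0)`).
#' @param K states to fit.
#' @param restarts EM restarts.
#' @param ... passed to [em_fit()].
#' @return A list with `fit`, `populations`, `efficiencies`, `truth`.
#' @export
run_population_recovery <- function(condition, n_bursts = 5000, seed = 1L,
                                    K = 4, restarts = 4, ...) {
  sim <- simulate_condition(condition, n_bursts, stage_seed(seed, 1))
  fit <- em_fit(sim$data, K = K, restarts = restarts,
                seed = stage_seed(seed, 0), ...)
  list(fit = fit,
       populations = steady_state(fit$model$rate_matrix),
       efficiencies = fit$model$efficiencies,
       truth = sim$model)
}

#' End-to-end synthetic titration run
#'
#' Simulates a ligand titration as a concentration-dependent mixture of the
#' apo and saturated macrostate fixtures, scores every burst with the
#' macrostate likelihood test, builds the endpoint-calibrated saturation
#' curve and fits the Hill equation.
#'
#' @param conc concentrations in micromolar (must include 0 and a
#'   saturating point).
#' @param n_bursts_per_conc bursts per concentration.
#' @param hill_n,hill_k parameters of the generating Hill law.
#' @param seed root seed.
#' @param model_apo,model_sat optional scoring models; default: the true
#'   fixture models (apo and atp).
#' @param n_boot bootstrap resamples for the saturation-point errors.
#' @return A list with `curve` (a `saturation_curve`), `hill` (a
#'   [hill_fit()]), `datasets` and the generating parameters.
#' @export
run_titration_recovery <- function(conc = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 5,
                                            10),
                                   n_bursts_per_conc = 2000,
                                   hill_n = 2.9, hill_k = 1.7, seed = 1L,
                                   model_apo = NULL, model_sat = NULL,
                                   n_boot = 1000) {
  fx_apo <- make_macrostate_fixture("apo")
  fx_sat <- make_macrostate_fixture("atp")
  sims <- simulate_titration(conc, hill_n, hill_k, fx_apo, fx_sat,
                             n_bursts_per_conc, seed = stage_seed(seed, 6))
  if (is.null(model_apo)) {
    model_apo <- h2mm_model(fx_apo$rate_matrix, fx_apo$efficiencies,
                            clock_period = fx_apo$clock_period)
  }
  if (is.null(model_sat)) {
    model_sat <- h2mm_model(fx_sat$rate_matrix, fx_sat$efficiencies,
                            clock_period = fx_sat$clock_period)
  }
  datasets <- lapply(sims, function(s) h2mm_data(s$stream, s$bursts))
  curve <- saturation_curve(datasets, model_apo, model_sat,
                            n_boot = n_boot, seed = stage_seed(seed, 7))
  hill <- hill_fit(curve)
  list(curve = curve, hill = hill, datasets = datasets,
       generating = list(conc = conc, hill_n = hill_n, hill_k = hill_k),
       truth = sims)
}
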