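#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by an eigendecomposition of `t(Q)` (the
#' null left-eigenvector), the same diagonalization route used to convert
#' fitted transition-rate matrices into steady-state microstate populations.
#'
#' @param Q K x K generator: non-negative off-diagonal rates (s^-1), rows
#'   summing to zero, irreducible.
#' @return Length-K stationary probability vector.
#' @export
steady_state <- function(Q) {
  Q <- as.matrix(Q)
  K <- nrow(Q)
  if (ncol(Q) != K) stop("Q must be square")
  if (K == 1) return(1)
  scale <- max(abs(Q), 1)
  if (max(abs(rowSums(Q))) > 1e-8 * scale) stop("Q rows must sum to zero")
  unreachable <- reducibility_check(Q)
  if (length(unreachable)) {
    stop("Q is reducible; states not in a single communicating class: ",
         paste(unreachable, collapse = ", "))
  }
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  pi <- v / sum(v)
  pi[abs(pi) < 1e-14] <- 0
  if (any(pi < 0)) stop("numerical failure: negative stationary entries")
  pi / sum(pi)
}

# States outside the single communicating class of the positive-rate graph
# (empty when Q is irreducible). Simple reachability via boolean powers.
reducibility_check <- function(Q) {
  A <- (Q > 0) & (row(Q) != col(Q))
  K <- nrow(Q)
  reach <- A | diag(TRUE, K)
  for (i in seq_len(ceiling(log2(max(K, 2))))) {
    reach <- (reach %*% reach) > 0
  }
  ok <- reach & t(reach)
  which(apply(ok, 1, function(r) !all(r)))
}

#' Adjacent-microstate equilibrium constants
#'
#' Computes `K(i -> i+1) = k(i -> i+1) / k(i+1 -> i)` for the ladder of
#' adjacent microstates `i = 1 .. K-1` from the off-diagonal rates of `Q`.
#' These are the "horizontal" constants of the two-macrostate thermodynamic
#' cycle. For a reversible chain they equal the stationary population ratios
#' `pi_{i+1} / pi_i`; fitted matrices need not be reversible, so the rate
#' ratio is always used and the population ratio is reported separately as a
#' diagnostic.
#'
#' @param Q rate matrix (s^-1).
#' @return A data frame with columns `i` (transition `i -> i+1`),
#'   `k_fwd`, `k_bwd`, `K_eq`, `K_pi` (population-ratio diagnostic, `NA`
#'   when the stationary solve fails) and `infinite` (zero backward rate).
#' @export
equilibrium_constants <- function(Q) {
  K <- nrow(Q)
  i <- seq_len(K - 1)
  k_fwd <- Q[cbind(i, i + 1)]
  k_bwd <- Q[cbind(i + 1, i)]
  pi <- tryCatch(steady_state(Q), error = function(e) rep(NA_real_, K))
  data.frame(
    i = i, k_fwd = k_fwd, k_bwd = k_bwd,
    K_eq = ifelse(k_bwd > 0, k_fwd / k_bwd, Inf),
    K_pi = pi[i + 1] / pi[i],
    infinite = k_bwd <= 0
  )
}

#' Closed thermodynamic cycle between two macrostates
#'
#' Joins the adjacent-microstate equilibrium constants of two macrostate
#' rate matrices (the tense/apo and relaxed/ATP fingerprints) into a closed
#' cycle: the relative vertical (T -> R) constants are
#' `alpha_i / alpha_1 = prod_{j < i} K_R(j -> j+1) / K_T(j -> j+1)`, so cycle
#' closure holds exactly by construction, and free-energy differences are
#' `ddG(i vs j) = -R T ln(alpha_i / alpha_j)` with
#' `R = 1.9872e-3 kcal mol^-1 K^-1`.
#'
#' @param Q_T rate matrix of the tense (apo) macrostate (s^-1).
#' @param Q_R rate matrix of the relaxed (ligand-saturated) macrostate.
#' @param temperature absolute temperature in kelvin; default 295.15 K
#'   (~22 degrees C).
#' @return An object of class `"thermo_cycle"`: a list with `table` (a data
#'   frame with columns `i`, `K_T`, `K_R`, `alpha_rel`, `ddG_kcal_mol` —
#'   `alpha_rel[i] = alpha_i / alpha_1`, `ddG_kcal_mol[i] = -RT
#'   ln(alpha_i/alpha_1)`), `temperature`, and the gas constant used.
#' @export
thermo_cycle <- function(Q_T, Q_R, temperature = 295.15) {
  R_gas <- 1.9872e-3  # kcal mol^-1 K^-1
  eq_T <- equilibrium_constants(Q_T)
  eq_R <- equilibrium_constants(Q_R)
  K <- nrow(Q_T)
  ratio <- eq_R$K_eq / eq_T$K_eq
  alpha_rel <- c(1, cumprod(ratio))
  ddg <- -R_gas * temperature * log(alpha_rel)
  structure(
    list(table = data.frame(i = seq_len(K), alpha_rel = alpha_rel,
                            ddG_kcal_mol = ddg),
         constants = data.frame(i = eq_T$i, K_T = eq_T$K_eq,
                                K_R = eq_R$K_eq),
         temperature = temperature, R_gas = R_gas),
    class = "thermo_cycle"
  )
}

#' @export
print.thermo_cycle <- function(x, ...) {
  cat("<thermo_cycle> T =", x$temperature, "K\n")
  print(merge(x$table, x$constants, by = "i", all.x = TRUE))
  invisible(x)
}

#' Free-energy difference from a ratio of equilibrium constants
#'
#' `ddG = -R T ln(ratio)` in kcal/mol.
#'
#' @param ratio ratio of equilibrium constants (> 0).
#' @param temperature kelvin.
#' @return Free-energy difference in kcal/mol.
#' @export
delta_delta_g <- function(ratio, temperature = 295.15) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  -1.9872e-3 * temperature * log(ratio)
}

#' Condition fingerprint of a fitted kinetic model
#'
#' Bundles a fitted rate matrix with its stationary populations, the shared
#' microstate efficiencies and the per-state mean dwell times
#' `1 / (-Q[i, i])` into a macrostate summary.
#'
#' @param Q fitted rate matrix (s^-1), states ordered by decreasing
#'   efficiency.
#' @param efficiencies shared per-state FRET efficiencies.
#' @param label condition label.
#' @return An object of class `"macrostate_model"`.
#' @export
macrostate_model <- function(Q, efficiencies, label = "") {
  pi <- steady_state(Q)
  structure(
    list(label = label, rate_matrix = Q, efficiencies = efficiencies,
         populations = pi, mean_dwell_s = 1 / (-diag(Q))),
    class = "macrostate_model"
  )
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat("<macrostate_model>", x$label, "\n")
  print(data.frame(state = seq_along(x$efficiencies),
                   E = x$efficiencies,
                   population = x$populations,
                   mean_dwell_us = 1e6 * x$mean_dwell_s))
  invisible(x)
}
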