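#' Ground-truth model for synthetic photon trajectories
#'
#' Describes the generative process the photon-by-photon analysis assumes: a
#' hidden continuous-time Markov chain over `K` conformational microstates
#' with generator `rate_matrix` (s^-1), each state emitting donor-excitation
#' photons that are acceptor-colored with probability `efficiencies[i]`
#' (its FRET efficiency). Bursts have exponentially distributed durations,
#' photons arrive as a Poisson process during the burst, and
#' acceptor-excitation photons (all acceptor-colored) provide the PIE
#' stoichiometry signal.
#'
#' @param rate_matrix K x K generator: non-negative off-diagonal rates in
#'   s^-1, rows summing to zero.
#' @param efficiencies length-K vector of per-state FRET efficiencies in
#'   \[0, 1\].
#' @param initial_distribution length-K probability vector for the state at
#'   burst start; default is the stationary distribution of `rate_matrix`.
#' @param burst_duration_mean mean burst duration in seconds (exponential).
#' @param photon_rate detected donor-excitation photon rate during a burst,
#'   photons/s.
#' @param aex_photon_rate detected acceptor-excitation photon rate,
#'   photons/s.
#' @param background_rates named numeric vector `c(D = ..., A = ...)` of
#'   uniform background photon rates per emission channel, photons/s.
#' @param clock_period instrument clock period in seconds.
#' @param label free-text condition label.
#' @return An object of class `"ground_truth_model"`.
#' @export
ground_truth_model <- function(rate_matrix, efficiencies,
                               initial_distribution = NULL,
                               burst_duration_mean = 1e-3,
                               photon_rate = 1e5,
                               aex_photon_rate = 1e5,
                               background_rates = c(D = 0, A = 0),
                               clock_period = 12.5e-9,
                               label = "") {
  Q <- as.matrix(rate_matrix)
  K <- nrow(Q)
  if (ncol(Q) != K) stop("rate_matrix must be square")
  offdiag <- Q[row(Q) != col(Q)]
  if (any(offdiag < 0)) stop("off-diagonal rates must be non-negative")
  if (max(abs(rowSums(Q))) > 1e-8 * max(1, max(abs(Q)))) {
    stop("rate_matrix rows must sum to zero")
  }
  if (length(efficiencies) != K ||
      any(efficiencies < 0 | efficiencies > 1)) {
    stop("efficiencies must be K values in [0, 1]")
  }
  if (is.null(initial_distribution)) {
    initial_distribution <- steady_state(Q)
  }
  if (length(initial_distribution) != K ||
      abs(sum(initial_distribution) - 1) > 1e-8) {
    stop("initial_distribution must be a length-K probability vector")
  }
  structure(
    list(n_states = K, rate_matrix = Q, efficiencies = efficiencies,
         initial_distribution = initial_distribution,
         burst_duration_mean = burst_duration_mean,
         photon_rate = photon_rate, aex_photon_rate = aex_photon_rate,
         background_rates = background_rates, clock_period = clock_period,
         label = label),
    class = "ground_truth_model"
  )
}

# Stationary populations (fractions) of the four microstates under each
# solution condition, as resolved by the global photon-by-photon HMM
# analysis of the GroEL subunit. Entries not individually resolved are
# completed from the unit-sum constraint (remainder split equally where two
# entries are missing).
macrostate_populations <- list(
  apo    = c(0.084, 0.551, 0.296, 0.070),
  atp    = c(0.048, 0.253, 0.584, 0.115),
  adp    = c(0.085, 0.446, 0.384, 0.085),
  atp_es = c(0.047, 0.047, 0.254, 0.652)
)

# Shared microstate FRET efficiencies, in decreasing order (state 1 = most
# compact/highest efficiency).
microstate_efficiencies <- c(0.850, 0.608, 0.419, 0.213)

#' Macrostate fixtures for the GroEL subunit
#'
#' Builds the ground-truth model for one of the four solution conditions
#' (macrostates) of the single-ring GroEL subunit: `apo`, `atp` (1 mM ATP),
#' `adp` (1 mM ADP) and `atp_es` (1 mM ATP + GroES). All four share the
#' microstate FRET efficiencies (0.850, 0.608, 0.419, 0.213); each has its
#' own stationary population vector `pi`. The generator is constructed as
#' `k_ij = c * pi_j` (i != j) with `c = 3000` s^-1, which has `pi` as its
#' stationary distribution analytically, satisfies detailed balance, and
#' relaxes on a single timescale `1/c ~ 333` microseconds — inside the
#' experimentally observed 300–500 microsecond exchange window.
#'
#' @param name one of `"apo"`, `"atp"`, `"adp"`, `"atp_es"`.
#' @param exchange_rate the scale `c` in s^-1 of the `k_ij = c * pi_j`
#'   construction.
#' @param ... passed to [ground_truth_model()] (burst duration, photon
#'   rates, background, clock period).
#' @return A [ground_truth_model()] with `K = 4`.
#' @export
make_macrostate_fixture <- function(name = c("apo", "atp", "adp", "atp_es"),
                                    exchange_rate = 3000, ...) {
  name <- match.arg(name)
  pi <- macrostate_populations[[name]]
  pi <- pi / sum(pi)  # printed percentages carry rounding (apo sums to 100.1)
  K <- length(pi)
  Q <- exchange_rate * matrix(pi, K, K, byrow = TRUE)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  ground_truth_model(Q, microstate_efficiencies,
                     initial_distribution = pi, label = name, ...)
}
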