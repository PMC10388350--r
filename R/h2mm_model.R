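#' Photon-by-photon hidden Markov model
#'
#' The inference model: `K` hidden conformational states exchanging on the
#' instrument clock with per-tick transition matrix `T = expm(Q *
#' clock_period)`, each state emitting donor-excitation photons that are
#' acceptor-colored with probability `efficiencies[i]`. The model is stored
#' in rate-matrix form (`Q`, s^-1) with the clock period; the per-tick
#' matrix and its powers are derived where needed.
#'
#' @param rate_matrix K x K generator in s^-1 (rows sum to zero,
#'   off-diagonals >= 0).
#' @param efficiencies length-K per-state FRET efficiencies in \[0, 1\].
#' @param initial_distribution length-K probability vector; default is the
#'   stationary distribution of `rate_matrix`.
#' @param clock_period seconds per clock tick.
#' @return An object of class `"h2mm_model"`.
#' @export
h2mm_model <- function(rate_matrix, efficiencies,
                       initial_distribution = NULL,
                       clock_period = 12.5e-9) {
  Q <- as.matrix(rate_matrix)
  K <- nrow(Q)
  stopifnot(ncol(Q) == K, length(efficiencies) == K)
  if (any(efficiencies < 0 | efficiencies > 1)) {
    stop("efficiencies must lie in [0, 1]")
  }
  if (is.null(initial_distribution)) {
    initial_distribution <- tryCatch(steady_state(Q),
                                     error = function(e) rep(1 / K, K))
  }
  structure(
    list(n_states = K, rate_matrix = Q, efficiencies = efficiencies,
         initial_distribution = initial_distribution,
         clock_period = clock_period),
    class = "h2mm_model"
  )
}

#' @export
print.h2mm_model <- function(x, ...) {
  cat("<h2mm_model> K =", x$n_states, ", clock period",
      format(x$clock_period), "s\n")
  cat("  E:", paste(sprintf("%.3f", x$efficiencies), collapse = ", "), "\n")
  cat("  p0:", paste(sprintf("%.3f", x$initial_distribution),
                     collapse = ", "), "\n")
  cat("  rate matrix (s^-1):\n")
  print(round(x$rate_matrix, 1))
  invisible(x)
}

# Emission matrix: column 1 donor, column 2 acceptor.
emission_matrix <- function(model) {
  cbind(1 - model$efficiencies, model$efficiencies)
}

# Per-tick transition matrix T = expm(Q * clock_period) via
# eigendecomposition (exact for diagonalizable Q, which every fixture and
# virtually every fitted matrix is).
tick_transition <- function(Q, clock_period) {
  e <- eigen(Q * clock_period)
  T <- Re(e$vectors %*% diag(exp(e$values), nrow(Q)) %*% solve(e$vectors))
  T[T < 0] <- 0
  T / rowSums(T)
}

# Q = logm(T) / clock_period via eigendecomposition, with the small-negative
# off-diagonal guard (entries >= -1e-10 * scale clamped to zero).
rate_from_tick <- function(T, clock_period) {
  e <- eigen(T)
  lam <- e$values
  # principal log; eigenvalues of a proper tick matrix are in (0, 1]
  Q <- Re(e$vectors %*% diag(log(lam), nrow(T)) %*% solve(e$vectors)) /
    clock_period
  off <- Q[row(Q) != col(Q)]
  scale <- max(abs(Q), 1)
  if (any(off < -1e-6 * scale)) {
    warning("matrix log produced substantially negative off-diagonal rates")
  }
  Q[row(Q) != col(Q) & Q < 0] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Canonical state order: decreasing FRET efficiency.
canonical_order <- function(model) {
  ord <- order(model$efficiencies, decreasing = TRUE)
  h2mm_model(model$rate_matrix[ord, ord, drop = FALSE],
             model$efficiencies[ord],
             model$initial_distribution[ord],
             model$clock_period)
}

#' Write / read a model as JSON
#'
#' Stores `n_states`, `clock_period_s`, `rate_matrix_s_inv`, `efficiencies`
#' and `initial_distribution`.
#'
#' @param model an [h2mm_model()].
#' @param path file path.
#' @return `path` (write) or an [h2mm_model()] (read).
#' @export
write_h2mm_model <- function(model, path) {
  jsonlite::write_json(
    list(n_states = model$n_states,
         clock_period_s = model$clock_period,
         rate_matrix_s_inv = model$rate_matrix,
         efficiencies = model$efficiencies,
         initial_distribution = model$initial_distribution),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_h2mm_model
#' @export
read_h2mm_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  h2mm_model(x$rate_matrix_s_inv, x$efficiencies,
             x$initial_distribution, x$clock_period_s)
}
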