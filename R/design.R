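#' Fraction of labeled complexes carrying exactly one labeled subunit
#'
#' For a homo-oligomer reassembled from a mixture of labeled and unlabeled
#' monomers, the number of labeled subunits per complex is binomial with
#' `n_subunits` trials and success probability `p` (a labeled:unlabeled
#' monomer ratio of 1:N gives `p = 1 / (N + 1)`). Single-molecule FRET
#' requires the observed complexes to carry exactly one labeled subunit,
#' so the design quantity is the conditional probability
#' `P(X = 1) / P(X >= 1)`.
#'
#' @param p labeled monomer fraction, `0 < p < 1`; or use `ratio`.
#' @param n_subunits subunits per complex (7 for a single chaperonin ring).
#' @param ratio optional labeled:unlabeled ratio `c(1, N)` or string
#'   `"1:N"`, overriding `p`.
#' @return The single-label fraction among labeled complexes.
#' @export
single_label_fraction <- function(p = NULL, n_subunits = 7, ratio = NULL) {
  if (!is.null(ratio)) {
    if (is.character(ratio)) {
      parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
      if (length(parts) != 2 || anyNA(parts)) stop("ratio must be 'a:b'")
      ratio <- parts
    }
    p <- ratio[1] / sum(ratio)
  }
  if (is.null(p)) stop("give p or ratio")
  if (p <= 0) stop("p = 0: no labeled complexes, fraction undefined")
  if (p > 1) stop("p must be at most 1")
  if (n_subunits < 1) stop("n_subunits must be at least 1")
  p1 <- stats::dbinom(1, n_subunits, p)
  p_any <- 1 - stats::dbinom(0, n_subunits, p)
  p1 / p_any
}

#' Förster distance-efficiency conversion
#'
#' The point-dipole Förster relation `E = 1 / (1 + (R / R0)^6)` and its
#' exact inverse `R = R0 * (1/E - 1)^(1/6)`. `R0` is the dye-pair Förster
#' radius (the distance at which E = 0.5), in the same length unit as `R`.
#'
#' @param r interdye distance (> 0).
#' @param r0 Förster radius (> 0).
#' @return `forster_efficiency`: transfer efficiency in (0, 1).
#' @export
forster_efficiency <- function(r, r0) {
  if (any(r <= 0) || any(r0 <= 0)) stop("distances must be positive")
  1 / (1 + (r / r0)^6)
}

#' @rdname forster_efficiency
#' @param e transfer efficiency, strictly between 0 and 1.
#' @return `distance_from_efficiency`: interdye distance.
#' @export
distance_from_efficiency <- function(e, r0) {
  if (any(r0 <= 0)) stop("r0 must be positive")
  if (any(e <= 0 | e >= 1)) {
    stop("efficiency must be strictly between 0 and 1 ",
         "(0 and 1 map to infinite/zero distance)")
  }
  r0 * (1 / e - 1)^(1 / 6)
}
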