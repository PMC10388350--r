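# Brute-force oracles for the photon-by-photon HMM: exhaustive sums over
# all state paths, with inter-photon propagation by repeated matrix
# multiplication. Only usable for K^n path enumerations at tiny n.

tick_matrix <- function(Q, clock_period) {
  fretstates:::tick_transition(Q, clock_period)
}

mat_power <- function(T, d) {
  R <- diag(nrow(T))
  for (i in seq_len(d)) R <- R %*% T
  R
}

brute_loglik <- function(T, B, p0, colors, gaps) {
  K <- nrow(T)
  n <- length(colors)
  Tg <- lapply(gaps, function(d) mat_power(T, d))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- p0[s[1]] * B[s[1], colors[1] + 1]
    if (n > 1) {
      for (i in 2:n) {
        p <- p * Tg[[i]][s[i - 1], s[i]] * B[s[i], colors[i] + 1]
      }
    }
    total <- total + p
  }
  log(total)
}

brute_viterbi <- function(T, B, p0, colors, gaps) {
  K <- nrow(T)
  n <- length(colors)
  Tg <- lapply(gaps, function(d) mat_power(T, d))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- log(p0[s[1]]) + log(B[s[1], colors[1] + 1])
    if (n > 1) {
      for (i in 2:n) {
        p <- p + log(Tg[[i]][s[i - 1], s[i]]) + log(B[s[i], colors[i] + 1])
      }
    }
    if (p > best) {
      best <- p
      best_path <- s
    }
  }
  list(loglik = best, path = best_path)
}

random_rate_matrix <- function(K, lo = 100, hi = 5000) {
  Q <- matrix(stats::runif(K * K, lo, hi), K, K)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

random_h2mm_model <- function(K, clock_period = 1e-6) {
  Q <- random_rate_matrix(K)
  E <- sort(stats::runif(K, 0.05, 0.95), decreasing = TRUE)
  h2mm_model(Q, E, clock_period = clock_period)
}

# Two-state exchange model used across validation tests.
two_state_model <- function(k12 = 2000, k21 = 2000, E = c(0.8, 0.2),
                            photon_rate = 1e5,
                            burst_duration_mean = 2e-3) {
  Q <- matrix(c(-k12, k12, k21, -k21), 2, 2, byrow = TRUE)
  ground_truth_model(Q, E, photon_rate = photon_rate,
                     burst_duration_mean = burst_duration_mean)
}

# absolute-deviation expectation for parameter-recovery comparisons
expect_within <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
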