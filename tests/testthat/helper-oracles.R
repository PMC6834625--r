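# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately naive (double loops, direct formulas) and
# kept free of any package internals.

# Chebyshev distance between m-length windows starting at i, j (1-based)
cheb_dist <- function(x, i, j, m) {
  max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
}

# Sample entropy by explicit template counting, self-matches excluded.
oracle_sampen <- function(x, m, r) {
  n_templates <- length(x) - m  # each m-template must extend to m+1
  A <- 0
  B <- 0
  for (i in seq_len(n_templates - 1)) {
    for (j in (i + 1):n_templates) {
      if (cheb_dist(x, i, j, m) <= r) {
        B <- B + 1
        if (cheb_dist(x, i, j, m + 1) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Approximate entropy: Phi_m - Phi_{m+1}, self-matches included.
oracle_apen_phi <- function(x, m, r) {
  n <- length(x) - m + 1
  logs <- numeric(n)
  for (i in seq_len(n)) {
    cnt <- 0
    for (j in seq_len(n)) {
      if (cheb_dist(x, i, j, m) <= r) cnt <- cnt + 1
    }
    logs[i] <- log(cnt / n)
  }
  mean(logs)
}

oracle_apen <- function(x, m, r) {
  oracle_apen_phi(x, m, r) - oracle_apen_phi(x, m + 1, r)
}

# Planar path length by explicit per-step Euclidean summation.
oracle_path_rd <- function(ap, ml) {
  tot <- 0
  for (i in 2:length(ap)) {
    tot <- tot + sqrt((ap[i] - ap[i - 1])^2 + (ml[i] - ml[i - 1])^2)
  }
  tot
}

# A small feature table with a planted class signal, for classifier tests:
# one informative column (mean shift `delta`) plus pure-noise columns.
make_planted_features <- function(n_per_class = 30, n_noise = 8, delta = 1,
                                  seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("HC", "MS_High"), each = n_per_class)
  d <- tibble::tibble(
    participant_id = sprintf("S%03d", seq_len(n)),
    risk_group = factor(lab, levels = c("HC", "MS_Low", "MS_Mod", "MS_High")),
    signal = rnorm(n) + ifelse(lab == "MS_High", delta, 0)
  )
  for (k in seq_len(n_noise)) d[[paste0("noise", k)]] <- rnorm(n)
  d
}
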