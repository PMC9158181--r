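# Independent oracles and fixture generators used across the test files.
# Everything here is deliberately written against the definitions, not by
# calling the package's own computational path.

# finite-difference delta-method oracle for the asymptotic variance of
# sqrt(n) * d_S(p_hat): gradient of d_S at (p11, p01, p10) by central
# differences, times the trinomial covariance of the estimated cells
delta_var_oracle <- function(p11, p01, p10, h = 1e-6) {
  ds <- function(v) 1 - 2 * v[1] / (2 * v[1] + v[2] + v[3])
  p <- c(p11, p01, p10)
  grad <- vapply(1:3, function(j) {
    e <- replace(numeric(3), j, h)
    (ds(p + e) - ds(p - e)) / (2 * h)
  }, numeric(1))
  Sigma <- diag(p) - tcrossprod(p)     # cov of sqrt(n)*(p_hat - p)
  drop(t(grad) %*% Sigma %*% grad)
}

# exhaustive hypergeometric tail P(X >= a) via binomial coefficients
hyper_tail_oracle <- function(a, K, m, N) {
  ks <- max(a, 0):min(K, m)
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, m - ks)) / choose(N, m)
}

# all permutations of 1..s, written independently of the package helper
perms_oracle <- function(s) {
  if (s == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(s - 1)) {
    for (pos in seq_len(s)) {
      out[[length(out) + 1L]] <-
        append(p, s, after = pos - 1L)
    }
  }
  out
}

# Holm step-down oracle: adjusted p-values computed from the definition
holm_oracle <- function(p) {
  h <- length(p)
  o <- order(p)
  adj <- numeric(h)
  running <- 0
  for (l in seq_len(h)) {
    running <- max(running, (h + 1 - l) * p[o[l]])
    adj[o[l]] <- min(1, running)
  }
  adj
}

# random non-degenerate joint-enrichment tables (studentized statistic
# defined: n11 > 0 and n10 + n01 > 0); uses the current RNG stream
random_tables <- function(k) {
  out <- vector("list", k)
  i <- 0L
  while (i < k) {
    n <- sample(50:3000, 1)
    alpha_dir <- stats::rgamma(4, shape = c(1, 0.6, 0.6, 3))
    p <- alpha_dir / sum(alpha_dir)
    cells <- stats::rmultinom(1, n, p)[, 1]
    if (cells[1] == 0 || cells[2] + cells[3] == 0) next
    i <- i + 1L
    out[[i]] <- enrich_table(cells[1], cells[2], cells[3], cells[4])
  }
  out
}
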