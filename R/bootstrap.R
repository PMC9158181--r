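#' Studentized-bootstrap distribution of the Sorensen-Dice statistic
#'
#' Approximates the sampling distribution of the studentized statistic
#' \eqn{\sqrt{n}(\hat d_S - d_S)/\hat\sigma_S} by resampling: each
#' replicate draws a table \eqn{(n^*_{11}, n^*_{01}, n^*_{10}, n^*_{00})}
#' from a multinomial of size `n` with the estimated probabilities
#' \eqn{\hat p}, and records
#' \eqn{\sqrt{n}(d_S(\hat p^*) - d_S(\hat p))/\hat\sigma^*_S}, where
#' \eqn{\hat\sigma^*_S} is the delta-method standard deviation of the
#' resampled table. Replicates on which the studentized statistic is
#' undefined (resampled `n11 = 0` or `n10 + n01 = 0`) are discarded, so
#' the effective number of replicates can fall below `B`; this mirrors
#' the exclusion rule of the simulation engine.
#'
#' All `B` tables are drawn in one vectorized pass from a single seeded
#' generator, so discarding invalid replicates does not perturb the
#' random stream of the remaining ones.
#'
#' @param table An [enrich_table()] (or anything [as_enrich_table()]
#'   accepts) on which the statistic is defined.
#' @param B Number of bootstrap replicates requested (`>= 1`).
#' @param seed Optional RNG seed; with a fixed seed the returned vector is
#'   reproducible bit for bit.
#' @return An object of class `boot_distribution`: a list with `stats`
#'   (the finite studentized values, length `B_effective`), `B_requested`,
#'   `B_effective` and `seed`.
#' @examples
#' bd <- boot_distribution(enrich_table(125, 50, 50, 775), B = 1000,
#'                         seed = 1)
#' bd
#' @export
boot_distribution <- function(table, B = 10000, seed = NULL) {
  tab <- as_enrich_table(table)
  check_number(B, "B", 1)
  est <- sorensen_estimate(tab)
  if (est$degenerate)
    undefined_statistic(
      "cannot bootstrap a degenerate table (estimated standard error is zero)")
  n <- est$n
  p_hat <- estimate_probs(tab)
  stats <- with_seed(seed, function() {
    boot_stats_fast(n, p_hat, est$d_hat, B)
  })
  if (length(stats) == 0L)
    sq_input_error(paste0(
      "all ", B, " bootstrap replicates were discarded (resampled tables ",
      "had zero cells); enrichment is too sparse, or increase B"))
  structure(list(stats = stats, B_requested = as.integer(B),
                 B_effective = length(stats), seed = seed),
            class = "boot_distribution")
}

# core resampler: draws B multinomial tables at size n and probabilities p
# (length 4, order p11, p01, p10, p00) and returns the finite studentized
# statistic values. Uses the current RNG stream.
boot_stats_fast <- function(n, p, d_hat, B) {
  draws <- stats::rmultinom(B, n, unclass(p))  # rows: n11, n01, n10, n00
  n11 <- draws[1L, ]; n01 <- draws[2L, ]; n10 <- draws[3L, ]
  ok <- n11 > 0L & (n01 + n10) > 0L
  n11 <- n11[ok]; n01 <- n01[ok]; n10 <- n10[ok]
  ds_star <- ds_cells(n11, n10, n01)
  sigma_star <- sqrt(sigma2_cells(n11 / n, n01 / n, n10 / n))
  sqrt(n) * (ds_star - d_hat) / sigma_star
}

#' @export
print.boot_distribution <- function(x, ...) {
  cat(sprintf(
    "Studentized-bootstrap distribution: %d effective / %d requested replicates\n",
    x$B_effective, x$B_requested))
  cat(sprintf("  mean = %.4f, sd = %.4f, 5%% quantile = %.4f\n",
              mean(x$stats), stats::sd(x$stats), boot_quantile(x, 0.05)))
  invisible(x)
}

#' Empirical quantile of a bootstrap distribution
#'
#' Returns the lower-`alpha` empirical quantile used by the bootstrap
#' equivalence test: the order statistic of rank
#' `floor(alpha * (B_effective + 1))`. This convention is the exact
#' inverse of the conservative bootstrap p-value
#' `(#\{stats <= t\} + 1) / (B_effective + 1)`, so the p-value route and
#' the interval-inclusion route of [sorensen_equiv_test()] always give
#' the same reject decision. When `alpha * (B_effective + 1) < 1` the
#' sample cannot resolve the tail and `-Inf` is returned (the test then
#' never rejects); use a larger `B`.
#'
#' @param bd A [boot_distribution()].
#' @param alpha Tail probability in `(0, 1)`.
#' @return The empirical quantile (a single number, possibly `-Inf`).
#' @export
boot_quantile <- function(bd, alpha) {
  check_alpha(alpha)
  k <- floor(alpha * (bd$B_effective + 1) + 1e-9)
  if (k < 1) return(-Inf)
  sort(bd$stats, partial = k)[k]
}
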