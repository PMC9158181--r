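#' Sorensen-Dice dissimilarity between two feature lists
#'
#' The dissimilarity is defined on the joint-enrichment probabilities as
#' \deqn{d_S = 1 - \frac{2 p_{11}}{2 p_{11} + p_{10} + p_{01}},}
#' i.e. one minus the Sorensen-Dice similarity of the two sets of enriched
#' terms. The double-negative probability `p00` never enters: terms
#' enriched in neither list carry no information about the biological
#' agreement of the lists and their count can be inflated arbitrarily by
#' enlarging the term universe.
#'
#' @param p11 Either an [enrich_probs()] vector (then `p01`, `p10` are
#'   ignored) or the joint-enrichment probability as a number.
#' @param p01,p10 Discordant-enrichment probabilities (when `p11` is a
#'   number). Vectorized over all three arguments.
#' @return Dissimilarity value(s) in `[0, 1]`.
#' @examples
#' sorensen_dissimilarity(0.125, 0.05, 0.05)   # 2/7
#' sorensen_dissimilarity(enrich_probs(0.5, 0.2, 0.2))
#' @export
sorensen_dissimilarity <- function(p11, p01 = NULL, p10 = NULL) {
  if (inherits(p11, "enrich_probs") ||
      (is.null(p01) && is.null(p10) && length(p11) >= 3L)) {
    p <- as_enrich_probs(p11)
    p11 <- p[["p11"]]; p01 <- p[["p01"]]; p10 <- p[["p10"]]
  }
  denom <- 2 * p11 + p10 + p01
  if (any(denom <= 0))
    undefined_statistic(
      "Sorensen-Dice dissimilarity undefined: p11 = p10 = p01 = 0")
  1 - 2 * p11 / denom
}

# vectorized, no validation: d_S from counts (or probabilities)
ds_cells <- function(n11, n10, n01) 1 - 2 * n11 / (2 * n11 + n10 + n01)

# vectorized, no validation: sigma^2_S from probabilities (per-sqrt(n) scale)
sigma2_cells <- function(p11, p01, p10) {
  4 * p11 * (p01 + p10) * (p11 + p01 + p10) / (2 * p11 + p01 + p10)^4
}

#' Delta-method asymptotic variance of the Sorensen-Dice estimator
#'
#' By the delta method, \eqn{\sqrt{n}(\hat d_S - d_S)} is asymptotically
#' normal with variance
#' \deqn{\sigma_S^2 = \frac{4 p_{11} (p_{01} + p_{10})
#'   (p_{11} + p_{01} + p_{10})}{(2 p_{11} + p_{01} + p_{10})^4}.}
#' The value is on the per-\eqn{\sqrt{n}} scale: the standard error of
#' \eqn{\hat d_S} is \eqn{\sigma_S / \sqrt{n}}.
#'
#' @inheritParams sorensen_dissimilarity
#' @return The asymptotic variance \eqn{\sigma_S^2}.
#' @examples
#' sorensen_variance(0.125, 0.05, 0.05)  # ~0.7497
#' @export
sorensen_variance <- function(p11, p01 = NULL, p10 = NULL) {
  if (inherits(p11, "enrich_probs") ||
      (is.null(p01) && is.null(p10) && length(p11) >= 3L)) {
    p <- as_enrich_probs(p11)
    p11 <- p[["p11"]]; p01 <- p[["p01"]]; p10 <- p[["p10"]]
  }
  if (any(2 * p11 + p01 + p10 <= 0))
    undefined_statistic("asymptotic variance undefined: p11 = p10 = p01 = 0")
  sigma2_cells(p11, p01, p10)
}

#' Sorensen-Dice point estimate with standard error
#'
#' Computes the plug-in dissimilarity estimate
#' \eqn{\hat d_S = 1 - 2 n_{11} / (2 n_{11} + n_{10} + n_{01})} and its
#' delta-method standard error \eqn{\hat\sigma_S / \sqrt{n}} from a
#' joint-enrichment table.
#'
#' When `n11 = 0` (so \eqn{\hat d_S = 1}) or `n10 + n01 = 0` (so
#' \eqn{\hat d_S = 0}) the variance estimate is exactly zero and the
#' studentized statistic is undefined; the returned estimate carries
#' `degenerate = TRUE` in that case, and downstream tests refuse it with a
#' typed undefined-statistic error. A table with all of `n11`, `n10`,
#' `n01` equal to zero admits no dissimilarity at all and raises the error
#' here.
#'
#' @param table An [enrich_table()] (or anything [as_enrich_table()]
#'   accepts).
#' @return An object of class `sorensen_estimate`: a list with elements
#'   `d_hat`, `sigma_hat` (per-\eqn{\sqrt{n}} scale), `se`
#'   (`sigma_hat/sqrt(n)`), `n` and `degenerate`.
#' @examples
#' sorensen_estimate(enrich_table(125, 50, 50, 775))
#' @export
sorensen_estimate <- function(table) {
  tab <- as_enrich_table(table)
  n11 <- tab[["n11"]]; n10 <- tab[["n10"]]; n01 <- tab[["n01"]]
  n <- attr(tab, "n")
  if (n11 + n10 + n01 == 0L)
    undefined_statistic(
      "no enriched terms in either list: the Sorensen-Dice dissimilarity is undefined")
  p <- estimate_probs(tab)
  d_hat <- ds_cells(n11, n10, n01)
  sigma_hat <- sqrt(sigma2_cells(p[["p11"]], p[["p01"]], p[["p10"]]))
  structure(list(d_hat = d_hat,
                 sigma_hat = sigma_hat,
                 se = sigma_hat / sqrt(n),
                 n = n,
                 degenerate = sigma_hat == 0),
            class = "sorensen_estimate")
}

#' @export
print.sorensen_estimate <- function(x, digits = 4, ...) {
  cat("Sorensen-Dice dissimilarity estimate\n")
  cat(sprintf("  d_hat = %.*f  (se = %.*f, n = %d terms)\n",
              digits, x$d_hat, digits, x$se, x$n))
  if (x$degenerate)
    cat("  NOTE: degenerate table (estimated standard error is zero)\n")
  invisible(x)
}

#' Asymptotic confidence interval for the Sorensen-Dice dissimilarity
#'
#' Normal-theory intervals based on the delta-method standard error. The
#' one-sided interval is \eqn{[0, \hat d_S + z_{1-\alpha} \hat\sigma_S /
#' \sqrt{n}]}; the two-sided one is \eqn{\hat d_S \pm z_{1-\alpha/2}
#' \hat\sigma_S / \sqrt{n}}. Limits are deliberately not clipped to
#' `[0, 1]`: the equivalence decision compares the upper limit with the
#' equivalence threshold on the real line. Use `clip = TRUE` for a
#' display-friendly clipped interval.
#'
#' @param est A [sorensen_estimate()].
#' @param alpha Significance level in `(0, 1)` (confidence `1 - alpha`).
#' @param sided `"one"` (default; upper confidence limit, the quantity
#'   used by the equivalence test) or `"two"`.
#' @param clip Clip the limits to `[0, 1]` for display. Default `FALSE`.
#' @return Numeric `c(lower, upper)` with attribute `conf.level`; for a
#'   degenerate estimate (zero standard error) the interval collapses to a
#'   point and carries attribute `degenerate = TRUE`.
#' @examples
#' est <- sorensen_estimate(enrich_table(125, 50, 50, 775))
#' sorensen_ci(est, alpha = 0.05, sided = "one")
#' @export
sorensen_ci <- function(est, alpha = 0.05, sided = c("one", "two"),
                        clip = FALSE) {
  if (!inherits(est, "sorensen_estimate"))
    est <- sorensen_estimate(est)
  check_alpha(alpha)
  sided <- match.arg(sided)
  if (sided == "one") {
    z <- stats::qnorm(1 - alpha)
    out <- c(0, est$d_hat + z * est$se)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    out <- c(est$d_hat - z * est$se, est$d_hat + z * est$se)
  }
  if (clip) out <- pmin(pmax(out, 0), 1)
  attr(out, "conf.level") <- 1 - alpha
  attr(out, "sided") <- sided
  if (est$degenerate) attr(out, "degenerate") <- TRUE
  out
}
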