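#' Equivalence (dissimilarity-irrelevance) test between two feature lists
#'
#' Tests \eqn{H_0: d_S \ge d_0} against \eqn{H_1: d_S < d_0} for the
#' Sorensen-Dice dissimilarity computed from a joint-enrichment table.
#' Rejecting \eqn{H_0} establishes that the dissimilarity between the two
#' lists is irrelevant up to the threshold `d0`, i.e. that the lists are
#' biologically equivalent at that level.
#'
#' Two flavours are available. The `"normal"` test uses the delta-method
#' asymptotics: the p-value is
#' \eqn{\Phi(\sqrt{n}(\hat d_S - d_0)/\hat\sigma_S)} and, by the interval
#' inclusion principle, rejection is equivalent to the one-sided
#' \eqn{1-\alpha} upper confidence limit falling below `d0`. The
#' `"bootstrap"` flavour replaces the normal distribution by the
#' studentized-bootstrap distribution of the statistic (see
#' [boot_distribution()]); it is better calibrated when enrichment is
#' sparse, where the normal test is anti-conservative.
#'
#' The threshold `d0` is always an analysis choice and has no default. It
#' may be supplied directly or through `rho`, the enrichment concordance
#' ratio (see [d0_from_rho()]).
#'
#' @param table An [enrich_table()] (or anything [as_enrich_table()]
#'   accepts).
#' @param d0 Equivalence limit in `(0, 1)`. Exactly one of `d0` and `rho`
#'   must be given.
#' @param alpha Significance level in `(0, 1)`. Default `0.05`.
#' @param method `"normal"` (delta-method asymptotics) or `"bootstrap"`
#'   (studentized bootstrap).
#' @param rho,rho_convention Alternative threshold specification routed
#'   through [d0_from_rho()].
#' @param B Bootstrap replicates (bootstrap method only). Default `10000`.
#' @param seed RNG seed for the bootstrap (bootstrap method only).
#' @return An object of class `equiv_sorensen_test`: a list with elements
#'   `d_hat`, `se`, `n`, `statistic` (the studentized statistic
#'   \eqn{\sqrt{n}(\hat d_S - d_0)/\hat\sigma_S}), `d_upper` (one-sided
#'   upper confidence limit), `p_value`, `reject`, `d0`, `alpha`, `method`
#'   and, for the bootstrap flavour, `boot_meta` (list with `B_requested`,
#'   `B_effective`, `seed`).
#' @examples
#' tab <- enrich_table(125, 50, 50, 775)
#' sorensen_equiv_test(tab, d0 = 0.4444)
#' sorensen_equiv_test(tab, rho = 1.25, rho_convention = "double")
#' sorensen_equiv_test(tab, d0 = 0.4444, method = "bootstrap",
#'                     B = 1000, seed = 1)
#' @references The interval inclusion principle: reject non-equivalence
#'   when the one-sided confidence interval for the dissimilarity lies
#'   entirely inside the equivalence region.
#' @export
sorensen_equiv_test <- function(table, d0 = NULL, alpha = 0.05,
                                method = c("normal", "bootstrap"),
                                rho = NULL,
                                rho_convention = c("double", "single"),
                                B = 10000, seed = NULL) {
  method <- match.arg(method)
  if (is.null(d0) && is.null(rho))
    sq_input_error("an equivalence limit is required: give `d0` or `rho`")
  if (!is.null(d0) && !is.null(rho))
    sq_input_error("`d0` and `rho` are mutually exclusive")
  if (is.null(d0)) d0 <- d0_from_rho(rho, match.arg(rho_convention))
  check_number(d0, "d0", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_alpha(alpha)
  tab <- as_enrich_table(table)
  est <- sorensen_estimate(tab)
  if (est$degenerate)
    undefined_statistic(sprintf(
      "studentized statistic undefined on table (n11=%d, n10=%d, n01=%d, n00=%d): estimated standard error is zero",
      tab[["n11"]], tab[["n10"]], tab[["n01"]], tab[["n00"]]))
  t_obs <- (est$d_hat - d0) / est$se
  if (method == "normal") {
    p_value <- stats::pnorm(t_obs)
    d_upper <- est$d_hat + stats::qnorm(1 - alpha) * est$se
    boot_meta <- NULL
  } else {
    bd <- boot_distribution(tab, B = B, seed = seed)
    p_value <- (sum(bd$stats <= t_obs) + 1) / (bd$B_effective + 1)
    d_upper <- est$d_hat - boot_quantile(bd, alpha) * est$se
    boot_meta <- list(B_requested = bd$B_requested,
                      B_effective = bd$B_effective, seed = bd$seed)
  }
  structure(list(d_hat = est$d_hat, se = est$se, n = est$n,
                 statistic = t_obs, d_upper = d_upper,
                 p_value = p_value, reject = p_value <= alpha,
                 d0 = d0, alpha = alpha, method = method,
                 boot_meta = boot_meta),
            class = "equiv_sorensen_test")
}

#' @export
print.equiv_sorensen_test <- function(x, digits = 4, ...) {
  cat("Sorensen-Dice equivalence test (",
      if (x$method == "normal") "asymptotic normal" else "studentized bootstrap",
      ")\n", sep = "")
  cat(sprintf("  H0: d_S >= %.4g  vs  H1: d_S < %.4g   (alpha = %g)\n",
              x$d0, x$d0, x$alpha))
  cat(sprintf("  d_hat = %.*f, se = %.*f, n = %d terms\n",
              digits, x$d_hat, digits, x$se, x$n))
  cat(sprintf("  one-sided upper %g%% confidence limit d_u = %.*f\n",
              100 * (1 - x$alpha), digits, x$d_upper))
  cat(sprintf("  p-value = %.4g -> %s\n", x$p_value,
              if (x$reject) "reject H0: lists equivalent up to d0"
              else "do not reject H0 (no evidence of equivalence)"))
  if (!is.null(x$boot_meta))
    cat(sprintf("  bootstrap: B = %d requested, %d effective%s\n",
                x$boot_meta$B_requested, x$boot_meta$B_effective,
                if (is.null(x$boot_meta$seed)) ""
                else sprintf(", seed = %d", x$boot_meta$seed)))
  invisible(x)
}

#' Equivalence limit from the enrichment concordance ratio
#'
#' A principled route to the (always arbitrary) equivalence limit `d0` is
#' a lower bound `rho` on the preponderance of joint over discordant
#' enrichment. Two conventions are in use:
#' * `"double"`: \eqn{\rho = 2 p_{11} / (p_{01} + p_{10})} (joint
#'   enrichment counted twice, matching the Sorensen-Dice definition),
#'   giving \eqn{d_0 = 1 / (1 + \rho)};
#' * `"single"`: \eqn{\rho = p_{11} / (p_{01} + p_{10})}, giving the
#'   stricter \eqn{d_0 = 1 / (1 + 2\rho)}.
#'
#' The bioequivalence-inspired reference ratios 10/8 and 10/9 translate to
#' limits 0.4444 and 0.4737 under the double convention, and 0.2857 and
#' 0.3103 under the single one.
#'
#' @param rho Concordance ratio, `> 0`. Vectorized.
#' @param convention `"double"` or `"single"`.
#' @return The equivalence limit in `(0, 1)`.
#' @examples
#' d0_from_rho(10/8, "double")   # 0.4444
#' d0_from_rho(10/9, "single")   # 0.3103
#' @export
d0_from_rho <- function(rho, convention = c("double", "single")) {
  convention <- match.arg(convention)
  if (!is.numeric(rho) || any(is.na(rho)) || any(rho <= 0))
    sq_input_error("`rho` must be positive")
  if (convention == "double") 1 / (1 + rho) else 1 / (1 + 2 * rho)
}

#' @rdname d0_from_rho
#' @param d0 Equivalence limit in `(0, 1)`. Vectorized.
#' @return `rho_from_d0()` returns the concordance ratio, the exact
#'   algebraic inverse of [d0_from_rho()].
#' @export
rho_from_d0 <- function(d0, convention = c("double", "single")) {
  convention <- match.arg(convention)
  if (!is.numeric(d0) || any(is.na(d0)) || any(d0 <= 0) || any(d0 >= 1))
    sq_input_error("`d0` must lie strictly inside (0, 1)")
  if (convention == "double") (1 - d0) / d0 else (1 - d0) / (2 * d0)
}

#' Joint-enrichment probability achieving a target dissimilarity
#'
#' Solves the Sorensen-Dice equation for `p11` given the discordant
#' probabilities: \eqn{p_{11} = (1 - d_S)(p_{10} + p_{01}) / (2 d_S)}.
#' Used to place simulation scenarios exactly on a desired dissimilarity
#' (e.g. on the equivalence boundary `d_S = d_0`).
#'
#' @param ds Target dissimilarity in `(0, 1]`.
#' @param p01,p10 Discordant-enrichment probabilities with
#'   `p01 + p10 > 0`.
#' @return `p11` such that `sorensen_dissimilarity(p11, p01, p10) == ds`.
#'   Errors if the resulting probability vector would be invalid
#'   (`p11 + p01 + p10 > 1`).
#' @examples
#' p11_for_target(0.2857, 0.005, 0.005)   # 0.0125 (within rounding of d_S)
#' @export
p11_for_target <- function(ds, p01, p10) {
  check_number(ds, "ds", 0, 1, strict_lower = TRUE)
  check_number(p01, "p01", 0, 1)
  check_number(p10, "p10", 0, 1)
  if (p01 + p10 <= 0)
    sq_input_error("`p01 + p10` must be positive to pin down p11")
  p11 <- (1 - ds) * (p10 + p01) / (2 * ds)
  if (p11 + p01 + p10 > 1 + 1e-12)
    sq_input_error(sprintf(
      "scenario (ds=%g, p01=%g, p10=%g) is infeasible: p11=%g makes the probabilities sum to %g > 1",
      ds, p01, p10, p11, p11 + p01 + p10))
  p11
}
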