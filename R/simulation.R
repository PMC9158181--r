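#' Generate a joint-enrichment table from the multinomial model
#'
#' `generate_table()` draws `(n11, n01, n10, n00)` in one step from a
#' multinomial of size `n` with probabilities `p`. In
#' `generate_table_twostage()` the number of enriched terms `nu` is first
#' drawn as a binomial of size `n` and probability
#' `Pr(E) = p11 + p01 + p10`, and then, conditional on `nu`,
#' `(n11, n01, n10)` as a multinomial of size `nu` with the renormalized
#' probabilities `p_ij / Pr(E)`; `n00 = n - nu`. The two schemes produce
#' identically distributed tables (the conditional decomposition of the
#' multinomial), which is verified by a goodness-of-fit property test.
#'
#' @param n Total number of terms (`>= 1`).
#' @param p An [enrich_probs()] vector (or anything coercible).
#' @param seed Optional RNG seed; `NULL` uses (and advances) the current
#'   stream, which is how the simulation engine calls it.
#' @return An [enrich_table()].
#' @examples
#' generate_table(1000, enrich_probs(0.125, 0.05, 0.05), seed = 1)
#' @export
generate_table <- function(n, p, seed = NULL) {
  check_number(n, "n", 1)
  p <- as_enrich_probs(p)
  with_seed(seed, function() {
    draw <- stats::rmultinom(1L, n, unclass(p))[, 1L]
    enrich_table(draw[1L], draw[3L], draw[2L], draw[4L])  # p order: 11,01,10,00
  })
}

#' @rdname generate_table
#' @export
generate_table_twostage <- function(n, p, seed = NULL) {
  check_number(n, "n", 1)
  p <- as_enrich_probs(p)
  pr_e <- p[["p11"]] + p[["p01"]] + p[["p10"]]
  if (pr_e <= 0)
    sq_input_error("two-stage generation needs Pr(enriched) = p11 + p01 + p10 > 0")
  with_seed(seed, function() {
    nu <- stats::rbinom(1L, n, pr_e)
    if (nu == 0L) return(enrich_table(0L, 0L, 0L, n))
    cell <- stats::rmultinom(1L, nu,
                             c(p[["p11"]], p[["p01"]], p[["p10"]]) / pr_e)[, 1L]
    enrich_table(cell[1L], cell[3L], cell[2L], n - nu)
  })
}

#' Define a Monte-Carlo scenario for the equivalence test
#'
#' A scenario fixes the table-generating law (`n` terms, joint-enrichment
#' probabilities), the test settings (`d0`, `alpha`, flavour) and the
#' replicate budget. `p11` may be given directly or derived from a target
#' dissimilarity `ds` via [p11_for_target()] — placing `ds = d0` puts the
#' scenario exactly on the equivalence boundary, where the rejection rate
#' estimates the type-I error probability.
#'
#' @param n Number of terms per simulated table.
#' @param p01,p10 Discordant-enrichment probabilities.
#' @param p11 Joint-enrichment probability; exactly one of `p11` and `ds`
#'   must be given.
#' @param ds Target Sorensen-Dice dissimilarity from which `p11` is
#'   solved.
#' @param d0 Equivalence limit of the test under study.
#' @param alpha Nominal significance level. Default `0.05`.
#' @param n_sim Requested simulation replicates. Default `1e5` for the
#'   normal flavour; use a smaller budget (e.g. `2e3`) for the bootstrap
#'   flavour, whose cost is `n_sim * B` test computations.
#' @param method Test flavour, `"normal"` or `"bootstrap"`.
#' @param B Bootstrap replicates per simulated table (bootstrap flavour).
#'   Default `2e3`.
#' @param seed Optional scenario seed (set by [run_grid()] from its
#'   master seed when absent).
#' @return A list of class `sim_scenario` with the fields above plus
#'   `dS_true` (the implied dissimilarity) and `E_nu` (expected number of
#'   enriched terms, `n * (p11 + p01 + p10)`).
#' @examples
#' simulation_scenario(n = 1000, p01 = 0.05, p10 = 0.05, ds = 0.2857,
#'                     d0 = 0.2857)
#' @export
simulation_scenario <- function(n, p01, p10, p11 = NULL, ds = NULL,
                                d0, alpha = 0.05, n_sim = 1e5,
                                method = c("normal", "bootstrap"),
                                B = 2e3, seed = NULL) {
  method <- match.arg(method)
  if (is.null(p11) == is.null(ds))
    sq_input_error("give exactly one of `p11` and `ds`")
  if (is.null(p11)) p11 <- p11_for_target(ds, p01, p10)
  p <- enrich_probs(p11, p01, p10)
  check_number(n, "n", 1)
  check_number(d0, "d0", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_alpha(alpha)
  check_number(n_sim, "n_sim", 1)
  structure(list(n = as.integer(n), p = p, d0 = d0, alpha = alpha,
                 dS_true = sorensen_dissimilarity(p),
                 E_nu = n * (p11 + p01 + p10),
                 n_sim = as.integer(n_sim), method = method,
                 B = as.integer(B), seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario (%s test): n = %d, p = (%g, %g, %g), dS = %.4f, d0 = %.4f\n",
    x$method, x$n, x$p[["p11"]], x$p[["p01"]], x$p[["p10"]],
    x$dS_true, x$d0))
  cat(sprintf("  alpha = %g, E(nu) = %.2f, n_sim = %d%s\n",
              x$alpha, x$E_nu, x$n_sim,
              if (x$method == "bootstrap") sprintf(", B = %d", x$B) else ""))
  invisible(x)
}

#' Estimate the rejection probability of the equivalence test
#'
#' Runs the Monte-Carlo study defined by a [simulation_scenario()]:
#' repeatedly generates joint-enrichment tables, applies the chosen test
#' flavour, and reports the proportion of rejections among the replicates
#' on which the statistic is defined. Replicates whose table has
#' `n11 = 0` or `n10 + n01 = 0` (studentized statistic undefined) are
#' excluded and counted: at the boundary `dS = d0` the rejection rate
#' estimates the type-I error probability, below it the power.
#'
#' @param scenario A [simulation_scenario()].
#' @param coverage Also estimate the coverage of the one-sided
#'   `1 - alpha` interval `[0, d_u]` for the true dissimilarity. Default
#'   `TRUE` (cheap).
#' @return A list of class `sim_result`: `rejection_rate`, `mc_se` (the
#'   binomial Monte-Carlo standard error), `n_sim_effective`, `coverage`
#'   (or `NA`), and `scenario`.
#' @examples
#' sc <- simulation_scenario(n = 1000, p01 = 0.05, p10 = 0.05,
#'                           ds = 0.2857, d0 = 0.2857, n_sim = 2000,
#'                           seed = 1)
#' run_scenario(sc)
#' @export
run_scenario <- function(scenario, coverage = TRUE) {
  if (!inherits(scenario, "sim_scenario"))
    sq_input_error("`scenario` must come from simulation_scenario()")
  sc <- scenario
  out <- with_seed(sc$seed, function() {
    if (sc$method == "normal") run_normal_sims(sc, coverage)
    else run_boot_sims(sc, coverage)
  })
  if (out$n_eff == 0L)
    sq_input_error("no effective simulation replicates: every generated table had zero cells")
  r <- out$n_rej / out$n_eff
  structure(list(rejection_rate = r,
                 mc_se = sqrt(r * (1 - r) / out$n_eff),
                 n_sim_effective = out$n_eff,
                 coverage = if (coverage) out$n_cov / out$n_eff else NA_real_,
                 scenario = sc),
            class = "sim_result")
}

# vectorized normal-test simulation; uses the current RNG stream
run_normal_sims <- function(sc, coverage) {
  draws <- stats::rmultinom(sc$n_sim, sc$n, unclass(sc$p))
  n11 <- draws[1L, ]; n01 <- draws[2L, ]; n10 <- draws[3L, ]
  ok <- n11 > 0L & (n01 + n10) > 0L
  n11 <- n11[ok]; n01 <- n01[ok]; n10 <- n10[ok]
  d_hat <- ds_cells(n11, n10, n01)
  se <- sqrt(sigma2_cells(n11 / sc$n, n01 / sc$n, n10 / sc$n) / sc$n)
  p_val <- stats::pnorm((d_hat - sc$d0) / se)
  n_cov <- if (coverage) {
    d_u <- d_hat + stats::qnorm(1 - sc$alpha) * se
    sum(d_u >= sc$dS_true)
  } else 0L
  list(n_rej = sum(p_val <= sc$alpha), n_eff = sum(ok), n_cov = n_cov)
}

# bootstrap-test simulation; one vectorized bootstrap per replicate
run_boot_sims <- function(sc, coverage) {
  draws <- stats::rmultinom(sc$n_sim, sc$n, unclass(sc$p))
  n <- sc$n
  n_rej <- 0L; n_eff <- 0L; n_cov <- 0L
  for (i in seq_len(sc$n_sim)) {
    n11 <- draws[1L, i]; n01 <- draws[2L, i]; n10 <- draws[3L, i]
    if (n11 == 0L || n01 + n10 == 0L) next
    n_eff <- n_eff + 1L
    d_hat <- ds_cells(n11, n10, n01)
    se <- sqrt(sigma2_cells(n11 / n, n01 / n, n10 / n) / n)
    p_hat <- c(n11, n01, n10, n - n11 - n01 - n10) / n
    st <- boot_stats_fast(n, p_hat, d_hat, sc$B)
    b_eff <- length(st)
    if (b_eff == 0L) { n_eff <- n_eff - 1L; next }
    t_obs <- (d_hat - sc$d0) / se
    p_val <- (sum(st <= t_obs) + 1) / (b_eff + 1)
    if (p_val <= sc$alpha) n_rej <- n_rej + 1L
    if (coverage) {
      k <- floor(sc$alpha * (b_eff + 1) + 1e-9)
      q <- if (k < 1) -Inf else sort(st, partial = k)[k]
      if (d_hat - q * se >= sc$dS_true) n_cov <- n_cov + 1L
    }
  }
  list(n_rej = n_rej, n_eff = n_eff, n_cov = n_cov)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Estimated rejection probability: %.4f (MC se %.4f, %d effective replicates)\n",
    x$rejection_rate, x$mc_se, x$n_sim_effective))
  if (!is.na(x$coverage))
    cat(sprintf("  one-sided CI coverage of true dS: %.4f\n", x$coverage))
  invisible(x)
}

#' Build a factorial grid of boundary scenarios
#'
#' Crosses equivalence limits, table sizes and discordant-probability
#' pairs into a list of [simulation_scenario()]s, solving `p11` so that
#' each scenario sits at a target dissimilarity (by default the boundary
#' `ds = d0`). Infeasible combinations (probabilities summing above 1)
#' are skipped with a message.
#'
#' @param d0 Vector of equivalence limits.
#' @param n Vector of table sizes.
#' @param p_disc Two-column matrix or data frame of `(p01, p10)` pairs.
#' @param ds Target dissimilarity; `NULL` (default) uses each `d0`.
#' @inheritParams simulation_scenario
#' @return A list of `sim_scenario` objects.
#' @examples
#' g <- scenario_grid(d0 = c(0.2857, 0.4444), n = c(500, 1000),
#'                    p_disc = cbind(p01 = 0.05, p10 = 0.05),
#'                    n_sim = 1000)
#' length(g)
#' @export
scenario_grid <- function(d0, n, p_disc, ds = NULL, alpha = 0.05,
                          n_sim = 1e5, method = c("normal", "bootstrap"),
                          B = 2e3) {
  method <- match.arg(method)
  p_disc <- as.matrix(p_disc)
  if (ncol(p_disc) != 2L)
    sq_input_error("`p_disc` must have two columns (p01, p10)")
  out <- list()
  for (d in d0) for (nn in n) for (r in seq_len(nrow(p_disc))) {
    target <- if (is.null(ds)) d else ds
    sc <- tryCatch(
      simulation_scenario(n = nn, p01 = p_disc[r, 1L], p10 = p_disc[r, 2L],
                          ds = target, d0 = d, alpha = alpha,
                          n_sim = n_sim, method = method, B = B),
      sorequiv_input_error = function(e) {
        message("skipping infeasible scenario: ", conditionMessage(e))
        NULL
      })
    if (!is.null(sc)) out[[length(out) + 1L]] <- sc
  }
  if (!length(out)) sq_input_error("the scenario grid is empty")
  out
}

#' Run a list of scenarios and tabulate the results
#'
#' Executes [run_scenario()] on each scenario, deriving a deterministic
#' child seed per scenario from the master `seed` (so the grid is
#' reproducible and the result does not depend on evaluation order).
#' Individual scenario failures are recorded in the `error` column and
#' the run continues.
#'
#' @param scenarios Non-empty list of [simulation_scenario()]s.
#' @param seed Master seed; expands to per-scenario seeds for scenarios
#'   that do not carry their own.
#' @param coverage Passed to [run_scenario()].
#' @param out_csv Optional path; the result table is also written there
#'   as CSV.
#' @return A data frame with one row per scenario: `d0`, `n`, `p11`,
#'   `p01`, `p10`, `dS_true`, `E_nu`, `alpha`, `method`,
#'   `rejection_rate`, `mc_se`, `n_sim_effective`, `coverage`, `error`.
#' @export
run_grid <- function(scenarios, seed = NULL, coverage = TRUE,
                     out_csv = NULL) {
  if (!is.list(scenarios) || !length(scenarios))
    sq_input_error("`scenarios` must be a non-empty list")
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (!inherits(sc, "sim_scenario"))
      sq_input_error(sprintf("element %d is not a simulation scenario", i))
    if (is.null(sc$seed) && !is.null(seed)) sc$seed <- derive_seed(seed, i)
    res <- tryCatch(run_scenario(sc, coverage = coverage),
                    error = function(e) e)
    failed <- inherits(res, "error")
    rows[[i]] <- data.frame(
      d0 = sc$d0, n = sc$n, p11 = sc$p[["p11"]], p01 = sc$p[["p01"]],
      p10 = sc$p[["p10"]], dS_true = sc$dS_true, E_nu = sc$E_nu,
      alpha = sc$alpha, method = sc$method,
      rejection_rate = if (failed) NA_real_ else res$rejection_rate,
      mc_se = if (failed) NA_real_ else res$mc_se,
      n_sim_effective = if (failed) NA_integer_ else res$n_sim_effective,
      coverage = if (failed) NA_real_ else res$coverage,
      error = if (failed) conditionMessage(res) else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv))
    utils::write.csv(out, out_csv, row.names = FALSE, quote = TRUE)
  out
}

#' Synthetic gene lists with a planted enrichment pattern
#'
#' Fixture generator for end-to-end testing of the over-representation
#' front-end: it constructs a gene universe, a collection of disjoint
#' gene sets (terms), and two gene lists engineered so that the expected
#' enrichment calls match a planted incidence pattern — `planted[1]`
#' terms enriched in both lists, `planted[2]` only in the first,
#' `planted[3]` only in the second, the remaining terms in neither.
#'
#' A list is built by taking a fraction `effect` of the member genes of
#' each term planted as enriched for it, plus `list_extra` background
#' genes drawn uniformly from the rest of the universe. With a strong
#' effect the planted terms are called enriched with near certainty,
#' while background terms only reach the (Bonferroni-corrected) cutoff
#' by rare sampling accidents.
#'
#' @param n_genes Universe size. Default 2000.
#' @param n_terms Number of terms (disjoint gene sets). Default 20.
#' @param planted Integer vector `(both, only1, only2)`; the counts must
#'   fit into `n_terms`.
#' @param effect Fraction of a planted term's genes placed in the list,
#'   in `(0, 1]`. Default 0.9.
#' @param term_size Genes per term. `n_terms * term_size` must not
#'   exceed `n_genes`. Default 40.
#' @param list_extra Background genes per list. Default 100.
#' @param seed Optional RNG seed.
#' @return A list with `lists` (named list of two gene vectors),
#'   `universe`, `sets` (a [gene_set_collection()]), and `truth` (the
#'   planted n_terms x 2 incidence matrix as an [enrich_profile()]).
#' @examples
#' fx <- synth_gene_lists(planted = c(5, 2, 2), seed = 1)
#' prof <- profile_from_lists(fx$lists, fx$universe, fx$sets)
#' build_table(prof, "list1", "list2")
#' @export
synth_gene_lists <- function(n_genes = 2000, n_terms = 20,
                             planted = c(5, 2, 2), effect = 0.9,
                             term_size = 40, list_extra = 100,
                             seed = NULL) {
  check_number(n_genes, "n_genes", 1)
  check_number(n_terms, "n_terms", 1)
  check_number(effect, "effect", 0, 1, strict_lower = TRUE)
  if (length(planted) != 3L || any(planted < 0) ||
      any(planted != round(planted)))
    sq_input_error("`planted` must be three non-negative integers (both, only1, only2)")
  if (sum(planted) > n_terms)
    sq_input_error("planted counts exceed the number of terms")
  if (n_terms * term_size > n_genes)
    sq_input_error(sprintf(
      "infeasible planting: %d terms x %d genes exceed the %d-gene universe",
      n_terms, term_size, n_genes))
  universe <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, function() {
    pool <- sample(universe)
    sets <- stats::setNames(
      split(pool[seq_len(n_terms * term_size)],
            rep(seq_len(n_terms), each = term_size)),
      sprintf("T%03d", seq_len(n_terms)))
    truth <- matrix(0L, n_terms, 2L,
                    dimnames = list(names(sets), c("list1", "list2")))
    idx <- seq_len(sum(planted))
    if (planted[1] > 0) truth[idx[seq_len(planted[1])], ] <- 1L
    if (planted[2] > 0)
      truth[idx[planted[1] + seq_len(planted[2])], 1L] <- 1L
    if (planted[3] > 0)
      truth[idx[planted[1] + planted[2] + seq_len(planted[3])], 2L] <- 1L
    make_list <- function(col) {
      core <- unlist(lapply(which(truth[, col] == 1L), function(t) {
        sample(sets[[t]], round(effect * term_size))
      }), use.names = FALSE)
      extra <- sample(setdiff(universe, core), list_extra)
      unique(c(core, extra))
    }
    list(lists = list(list1 = make_list(1L), list2 = make_list(2L)),
         universe = universe,
         sets = gene_set_collection(sets),
         truth = enrich_profile(truth))
  })
}
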