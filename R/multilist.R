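#' All-pairs (or versus-reference) equivalence testing with FWER control
#'
#' Runs the Sorensen-Dice equivalence test on every pair of lists in an
#' enrichment profile (`h = s(s-1)/2` tests), or on every list against a
#' reference (`h = s - 1` tests), and corrects the p-values for testing
#' multiplicity. With a moderate number of comparisons the family-wise
#' error rate is controlled by Holm's step-down procedure (the default);
#' Benjamini-Hochberg FDR is offered for large families, and `"none"`
#' disables adjustment.
#'
#' Pairs whose joint-enrichment table leaves the studentized statistic
#' undefined (no jointly enriched terms or no discordant terms) are
#' flagged `testable = FALSE`, excluded from the multiplicity family, and
#' reported with `NA` test columns.
#'
#' @param profile An [enrich_profile()] with at least two lists.
#' @param d0 Equivalence limit in `(0, 1)` (or use `rho`).
#' @param alpha Family significance level. Default `0.05`.
#' @param method `"normal"` or `"bootstrap"`.
#' @param mode `"all-pairs"` (default) or `"vs-reference"`.
#' @param ref Reference list id (required for `mode = "vs-reference"`).
#' @param adjust `"holm"` (default), `"bh"` or `"none"`.
#' @param rho,rho_convention Alternative threshold via [d0_from_rho()].
#' @param B,seed Bootstrap settings; each pair gets a deterministic child
#'   seed derived from `seed`.
#' @return An object of class `pairwise_equiv` extending `data.frame`:
#'   one row per pair with columns `list1`, `list2`, `n11`, `n10`, `n01`,
#'   `n00`, `d_hat`, `d_upper`, `p_raw`, `p_adj`, `reject`, `testable`.
#'   Attributes `list_ids`, `d0`, `alpha`, `method`, `adjust`,
#'   `h` (number of testable comparisons).
#' @examples
#' set.seed(1)
#' inc <- matrix(rbinom(300, 1, 0.3), 100, 3,
#'               dimnames = list(NULL, c("A", "B", "C")))
#' pairwise_equiv_tests(enrich_profile(inc), d0 = 0.5)
#' @export
pairwise_equiv_tests <- function(profile, d0 = NULL, alpha = 0.05,
                                 method = c("normal", "bootstrap"),
                                 mode = c("all-pairs", "vs-reference"),
                                 ref = NULL,
                                 adjust = c("holm", "bh", "none"),
                                 rho = NULL,
                                 rho_convention = c("double", "single"),
                                 B = 10000, seed = NULL) {
  if (!inherits(profile, "enrich_profile")) profile <- enrich_profile(profile)
  method <- match.arg(method)
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (is.null(d0)) {
    if (is.null(rho))
      sq_input_error("an equivalence limit is required: give `d0` or `rho`")
    d0 <- d0_from_rho(rho, match.arg(rho_convention))
  }
  check_number(d0, "d0", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_alpha(alpha)
  ids <- colnames(profile)
  if (length(ids) < 2L)
    sq_input_error("at least two lists are required")
  if (mode == "vs-reference") {
    if (is.null(ref) || !ref %in% ids)
      sq_input_error("`ref` must name one of the profile's lists")
    pairs <- cbind(ref, setdiff(ids, ref))
  } else {
    idx <- utils::combn(length(ids), 2L)
    pairs <- cbind(ids[idx[1L, ]], ids[idx[2L, ]])
  }
  k <- nrow(pairs)
  res <- data.frame(list1 = pairs[, 1L], list2 = pairs[, 2L],
                    n11 = NA_integer_, n10 = NA_integer_,
                    n01 = NA_integer_, n00 = NA_integer_,
                    d_hat = NA_real_, d_upper = NA_real_,
                    p_raw = NA_real_, p_adj = NA_real_,
                    reject = NA, testable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    tab <- build_table(profile, pairs[i, 1L], pairs[i, 2L])
    res[i, c("n11", "n10", "n01", "n00")] <- as.list(unclass(tab))
    tst <- tryCatch(
      sorensen_equiv_test(tab, d0 = d0, alpha = alpha, method = method,
                          B = B,
                          seed = if (is.null(seed)) NULL
                                 else derive_seed(seed, i)),
      sorequiv_undefined_statistic = function(e) NULL)
    if (!is.null(tst)) {
      res$d_hat[i] <- tst$d_hat
      res$d_upper[i] <- tst$d_upper
      res$p_raw[i] <- tst$p_value
      res$testable[i] <- TRUE
    }
  }
  ok <- res$testable
  if (any(ok)) {
    res$p_adj[ok] <- stats::p.adjust(
      res$p_raw[ok],
      method = switch(adjust, holm = "holm", bh = "BH", none = "none"))
    res$reject[ok] <- res$p_adj[ok] <= alpha
  }
  structure(res,
            list_ids = ids, d0 = d0, alpha = alpha, method = method,
            adjust = adjust, h = sum(ok),
            class = c("pairwise_equiv", "data.frame"))
}

#' @export
print.pairwise_equiv <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Pairwise Sorensen-Dice equivalence tests (%s, %s adjustment)\n",
    attr(x, "method"), attr(x, "adjust")))
  cat(sprintf("  d0 = %.4g, alpha = %g, %d testable comparison(s) of %d\n",
              attr(x, "d0"), attr(x, "alpha"), attr(x, "h"), nrow(x)))
  if (any(!x$testable))
    cat("  (pairs with undefined statistic excluded from the family)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Triangular matrix of a pairwise test output
#'
#' Arranges one column of a [pairwise_equiv_tests()] result (by default
#' the one-sided upper confidence limits) as a symmetric s x s matrix,
#' the shape consumed by [mantel_cor()] when comparing the output of two
#' testing approaches over the same lists.
#'
#' @param pw A `pairwise_equiv` object from an all-pairs run.
#' @param value Column to spread: `"d_upper"` (default), `"d_hat"`,
#'   `"p_raw"`, `"p_adj"` or `"reject"`.
#' @return A symmetric numeric matrix with the list ids as dimnames and
#'   `NA` on the diagonal.
#' @export
pairwise_matrix <- function(pw, value = c("d_upper", "d_hat", "p_raw",
                                          "p_adj", "reject")) {
  value <- match.arg(value)
  ids <- attr(pw, "list_ids")
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (i in seq_len(nrow(pw))) {
    v <- as.numeric(pw[[value]][i])
    m[pw$list1[i], pw$list2[i]] <- v
    m[pw$list2[i], pw$list1[i]] <- v
  }
  m
}

#' Mantel permutation test between two triangular matrices
#'
#' Pearson correlation between the lower triangles of two symmetric
#' matrices indexed by the same lists (e.g. upper confidence limits from
#' two different equivalence-testing approaches), with significance
#' assessed by permuting the list labels of one matrix. The p-value is
#' two-sided: `(#\{|r_perm| >= |r_obs|\} + 1) / (permutations + 1)`.
#'
#' @param X,Y Symmetric numeric matrices of identical dimension `s >= 3`
#'   over the same lists in the same order; diagonals are ignored.
#' @param permutations Number of random label permutations. Default 999.
#' @param seed Optional RNG seed.
#' @param exact If `TRUE`, enumerate all `s!` label permutations instead
#'   of sampling and return the exact permutation p-value
#'   `#\{|r_perm| >= |r_obs|\} / s!` (identity included); only allowed for
#'   `s <= 7`.
#' @return A list of class `mantel_cor` with `r` (the observed
#'   correlation), `p_value`, `permutations` and `exact`.
#' @examples
#' set.seed(2)
#' X <- as.matrix(dist(matrix(rnorm(12), 4)))
#' Y <- X + as.matrix(dist(matrix(rnorm(12), 4))) / 5
#' mantel_cor(X, Y, permutations = 499, seed = 1)
#' @export
mantel_cor <- function(X, Y, permutations = 999, seed = NULL,
                       exact = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  s <- nrow(X)
  if (ncol(X) != s || !all(dim(Y) == s))
    sq_input_error("`X` and `Y` must be square matrices of the same size")
  if (s < 3L)
    sq_input_error("at least 3 lists are required for a Mantel test")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    sq_input_error("`X` and `Y` must be indexed by the same lists in the same order")
  low <- lower.tri(X)
  x <- X[low]
  if (stats::sd(x) == 0 || stats::sd(Y[low]) == 0)
    undefined_statistic("Mantel correlation undefined: a matrix is constant")
  r_for <- function(perm) stats::cor(x, Y[perm, perm][low])
  r_obs <- r_for(seq_len(s))
  if (exact) {
    if (s > 7L) sq_input_error("exact enumeration is limited to s <= 7 lists")
    perms <- all_permutations(s)
    r_perm <- vapply(perms, r_for, numeric(1))
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    n_perm <- length(perms)
  } else {
    check_number(permutations, "permutations", 1)
    r_perm <- with_seed(seed, function()
      vapply(seq_len(permutations),
             function(i) r_for(sample.int(s)), numeric(1)))
    p <- (sum(abs(r_perm) >= abs(r_obs) - 1e-12) + 1) / (permutations + 1)
    n_perm <- permutations
  }
  structure(list(r = r_obs, p_value = p, permutations = n_perm,
                 exact = exact),
            class = "mantel_cor")
}

#' @export
print.mantel_cor <- function(x, ...) {
  cat(sprintf(
    "Mantel test: r = %.4f, two-sided p = %.4g (%d %s permutations)\n",
    x$r, x$p_value, x$permutations,
    if (x$exact) "exhaustive" else "random"))
  invisible(x)
}

# all permutations of 1..s as a list of integer vectors
all_permutations <- function(s) {
  if (s == 1L) return(list(1L))
  sub <- all_permutations(s - 1L)
  out <- vector("list", s * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(s)) {
      k <- k + 1L
      out[[k]] <- append(p, s, after = pos - 1L)
    }
  }
  out
}
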