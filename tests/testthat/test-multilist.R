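make_profile <- function(nt, ids, p = 0.35) {
  inc <- matrix(rbinom(nt * length(ids), 1, p), nt, length(ids),
                dimnames = list(NULL, ids))
  enrich_profile(inc)
}

test_that("pairwise testing enumerates pairs and applies Holm correctly", {
  set.seed(31)
  prof <- make_profile(400, c("A", "B", "C", "D"))
  pw <- pairwise_equiv_tests(prof, d0 = 0.6, alpha = 0.05)
  expect_s3_class(pw, "pairwise_equiv")
  expect_equal(nrow(pw), 6)                       # 4*3/2 pairs
  expect_equal(attr(pw, "h"), 6)
  expect_true(all(pw$testable))

  # adjusted p-values equal the Holm step-down oracle over the family
  expect_equal(pw$p_adj, holm_oracle(pw$p_raw))
  expect_true(all(pw$p_adj >= pw$p_raw))
  expect_true(all(diff(pw$p_adj[order(pw$p_raw)]) >= -1e-15))
  expect_identical(pw$reject, pw$p_adj <= 0.05)

  # each row matches a single-pair test
  one <- sorensen_equiv_test(build_table(prof, "A", "B"), d0 = 0.6)
  expect_equal(pw$p_raw[pw$list1 == "A" & pw$list2 == "B"], one$p_value)
  expect_equal(pw$d_hat[pw$list1 == "A" & pw$list2 == "B"], one$d_hat)

  # vs-reference mode: s - 1 comparisons
  pv <- pairwise_equiv_tests(prof, d0 = 0.6, mode = "vs-reference",
                             ref = "B")
  expect_equal(nrow(pv), 3)
  expect_true(all(pv$list1 == "B"))
  expect_error(pairwise_equiv_tests(prof, d0 = 0.6, mode = "vs-reference",
                                    ref = "Z"),
               class = "sorequiv_input_error")
})

test_that("multiplicity-correction dominance: bonferroni <= holm <= unadjusted", {
  set.seed(32)
  for (i in 1:20) {
    prof <- make_profile(sample(100:600, 1), c("A", "B", "C", "D"),
                         p = runif(1, 0.1, 0.5))
    d0 <- runif(1, 0.3, 0.8)
    holm <- pairwise_equiv_tests(prof, d0 = d0, adjust = "holm")
    none <- pairwise_equiv_tests(prof, d0 = d0, adjust = "none")
    rej_h <- which(holm$reject); rej_n <- which(none$reject)
    expect_true(all(rej_h %in% rej_n))
    bonf <- which(none$p_raw <= 0.05 / attr(none, "h"))
    expect_true(all(bonf %in% rej_h))
  }
})

test_that("single-pair families and degenerate pairs are handled", {
  set.seed(33)
  prof <- make_profile(300, c("A", "B"))
  pw <- pairwise_equiv_tests(prof, d0 = 0.5)
  expect_equal(pw$p_adj, pw$p_raw)               # h = 1: no multiplicity

  # a list with no enrichment at all makes its pairs untestable
  inc <- cbind(unclass(make_profile(300, c("A", "B"))),
               C = rep(0L, 300))
  pw2 <- pairwise_equiv_tests(enrich_profile(inc), d0 = 0.5)
  bad <- pw2$list1 == "C" | pw2$list2 == "C"
  expect_true(all(!pw2$testable[bad]))
  expect_true(all(is.na(pw2$p_raw[bad])))
  expect_equal(attr(pw2, "h"), sum(!bad))
  # the testable sub-family is still Holm-adjusted among itself
  expect_equal(pw2$p_adj[!bad], holm_oracle(pw2$p_raw[!bad]))
})

test_that("pairwise_matrix lays results out symmetrically", {
  set.seed(34)
  prof <- make_profile(400, c("A", "B", "C"))
  pw <- pairwise_equiv_tests(prof, d0 = 0.6)
  m <- pairwise_matrix(pw, "d_upper")
  expect_true(isSymmetric(m))
  expect_true(all(is.na(diag(m))))
  expect_equal(m["A", "C"],
               pw$d_upper[pw$list1 == "A" & pw$list2 == "C"])
})

test_that("mantel_cor recovers exact identities and enumerated p-values", {
  set.seed(35)
  X <- as.matrix(dist(matrix(rnorm(15), 5)))
  expect_equal(mantel_cor(X, X, permutations = 99, seed = 1)$r, 1)
  expect_equal(mantel_cor(X, -X, permutations = 99, seed = 1)$r, -1)

  # 4 lists: exhaustive enumeration over the 24 label permutations,
  # recomputed here from scratch as the oracle
  Y <- as.matrix(dist(matrix(rnorm(12), 4)))
  Z <- as.matrix(dist(matrix(rnorm(12), 4)))
  res <- mantel_cor(Y, Z, exact = TRUE)
  low <- lower.tri(Y)
  r_all <- vapply(perms_oracle(4), function(p)
    cor(Y[low], Z[p, p][low]), numeric(1))
  expect_equal(res$permutations, 24)
  expect_equal(res$p_value, mean(abs(r_all) >= abs(res$r) - 1e-12))

  # constant matrices are refused with a typed signal
  expect_error(mantel_cor(matrix(1, 4, 4), Y, permutations = 9),
               class = "sorequiv_undefined_statistic")
})

test_that("mantel_cor is symmetric and relabeling-invariant", {
  set.seed(36)
  X <- as.matrix(dist(matrix(rnorm(18), 6)))
  Y <- as.matrix(dist(matrix(rnorm(18), 6)))
  expect_equal(mantel_cor(X, Y, permutations = 9, seed = 2)$r,
               mantel_cor(Y, X, permutations = 9, seed = 2)$r)
  perm <- sample(6)
  expect_equal(mantel_cor(X[perm, perm], Y[perm, perm],
                          permutations = 9, seed = 2)$r,
               mantel_cor(X, Y, permutations = 9, seed = 2)$r)
  # statistic cross-check against an established implementation
  skip_if_not_installed("vegan")
  expect_equal(mantel_cor(X, Y, permutations = 9, seed = 2)$r,
               unname(vegan::mantel(X, Y, permutations = 9)$statistic))
})
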