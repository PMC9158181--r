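test_that("ora_test p-values match exhaustive enumeration on tiny universes", {
  # all-in case: 1 / C(20,5)
  sets <- gene_set_collection(list(T1 = paste0("g", 1:5)))
  res <- ora_test(paste0("g", 1:5), paste0("g", 1:20), sets)
  expect_equal(res$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$a, 5L)
  expect_equal(res$K, 5L)

  # randomized universes up to 25 genes vs the binomial-coefficient oracle
  set.seed(51)
  for (i in 1:50) {
    N <- sample(8:25, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(1:N, 1)
    m <- sample(1:N, 1)
    term <- sample(universe, K)
    lst <- sample(universe, m)
    sets <- gene_set_collection(list(T = term))
    res <- ora_test(lst, universe, sets)
    a <- length(intersect(term, lst))
    expect_equal(res$p_raw, hyper_tail_oracle(a, K, m, N),
                 tolerance = 1e-12)
  }
})

test_that("ora_test agrees with one-sided Fisher's exact test", {
  universe <- paste0("g", 1:100)
  term <- universe[1:20]
  lst <- universe[c(1:12, 60:77)]
  sets <- gene_set_collection(list(T = term))
  res <- ora_test(lst, universe, sets)
  a <- length(intersect(term, lst)); m <- length(lst)
  ft <- fisher.test(matrix(c(a, length(term) - a,
                             m - a, 100 - length(term) - (m - a)), 2),
                    alternative = "greater")
  expect_equal(res$p_raw, ft$p.value, tolerance = 1e-12)
})

test_that("ora_test boundary behaviour and monotonicity in a", {
  # no overlap: tail from zero is 1
  sets <- gene_set_collection(list(T = paste0("g", 1:5)))
  res0 <- ora_test(paste0("g", 10:14), paste0("g", 1:20), sets)
  expect_equal(res0$p_raw, 1)
  expect_false(res0$enriched)

  # term = universe: any list hits all of it, p = 1
  setsN <- gene_set_collection(list(T = paste0("g", 1:20)))
  resN <- ora_test(paste0("g", 1:7), paste0("g", 1:20), setsN)
  expect_equal(resN$a, 7L)
  expect_equal(resN$p_raw, 1)

  # p_raw non-increasing in the overlap a for fixed N, K, m
  ps <- vapply(0:10, function(a) hyper_tail_oracle(a, 10, 10, 25),
               numeric(1))
  impl <- phyper(0:10 - 1, 10, 15, 10, lower.tail = FALSE)
  expect_equal(impl, ps, tolerance = 1e-12)
  expect_true(all(diff(impl) <= 1e-15))
})

test_that("ora_test handles universe violations and adjustment choices", {
  sets <- gene_set_collection(list(T1 = paste0("g", 1:5),
                                   T2 = paste0("g", 6:10),
                                   T3 = paste0("g", 11:15)))
  universe <- paste0("g", 1:20)
  expect_message(res <- ora_test(c(paste0("g", 1:5), "zz"), universe, sets),
                 "outside the universe")
  expect_equal(res$m[1], 5L)
  expect_error(ora_test(c("zz", "yy"), universe, sets),
               class = "sorequiv_input_error")

  # bonferroni-enriched calls are a subset of BH-enriched calls
  set.seed(52)
  for (i in 1:20) {
    lst <- sample(universe, sample(3:12, 1))
    bf <- ora_test(lst, universe, sets, adjust = "bonferroni")
    bh <- ora_test(lst, universe, sets, adjust = "bh")
    expect_true(all(bf$p_adj >= bh$p_adj))
    expect_true(all(which(bf$enriched) %in% which(bh$enriched)))
  }
})

test_that("gmt files round-trip through read_gmt / write_gmt", {
  sets <- gene_set_collection(
    list(T1 = c("a", "b", "c"), T2 = c("d", "e")),
    descriptions = c(T1 = "first", T2 = "second"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(unclass(back), unclass(sets), ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions")[["T1"]], "first")
  # a line without genes is malformed
  writeLines("T1\tdesc", f)
  expect_error(read_gmt(f), class = "sorequiv_input_error")
})

test_that("profile_from_lists produces the incidence of independent ORA calls", {
  fx <- synth_gene_lists(planted = c(4, 2, 1), seed = 53)
  prof <- profile_from_lists(fx$lists, fx$universe, fx$sets)
  expect_s3_class(prof, "enrich_profile")
  expect_equal(dim(prof), c(length(fx$sets), 2L))

  # identical lists give identical columns, hence zero discordance
  prof2 <- profile_from_lists(list(a = fx$lists$list1, b = fx$lists$list1),
                              fx$universe, fx$sets)
  tab <- build_table(prof2, "a", "b")
  expect_equal(tab[["n10"]], 0L)
  expect_equal(tab[["n01"]], 0L)

  # a list with no term overlap yields an all-zero column
  off_term <- setdiff(fx$universe, unlist(fx$sets))
  prof3 <- profile_from_lists(list(a = fx$lists$list1,
                                   b = off_term[1:50]),
                              fx$universe, fx$sets)
  expect_equal(sum(prof3[, "b"]), 0L)
})
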