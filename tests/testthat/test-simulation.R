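test_that("generate_table draws from the multinomial law deterministically", {
  p <- enrich_probs(0, 0, 0, 1)
  tab <- generate_table(50, p, seed = 61)
  expect_equal(as.vector(unclass(tab)), c(0L, 0L, 0L, 50L))

  # fixed seed -> reproducible table
  p2 <- enrich_probs(0.0125, 0.005, 0.005)
  expect_identical(generate_table(1000, p2, seed = 62),
                   generate_table(1000, p2, seed = 62))

  # mean of n11 over many draws within 3 binomial SE of n * p11
  set.seed(63)
  n11s <- replicate(1e4, generate_table(1000, p2)[["n11"]])
  se <- sqrt(1000 * 0.0125 * (1 - 0.0125) / 1e4)
  expect_lt(abs(mean(n11s) - 12.5), 3 * se)
})

test_that("the two-stage generator has the same law as the one-stage one", {
  p <- enrich_probs(0.2, 0.1, 0.1, 0.6)
  # Pr(E) = 1 forces nu = n
  p_full <- enrich_probs(0.5, 0.25, 0.25, 0)
  tab <- generate_table_twostage(30, p_full, seed = 64)
  expect_equal(tab[["n00"]], 0L)
  expect_identical(generate_table_twostage(50, p, seed = 65),
                   generate_table_twostage(50, p, seed = 65))

  # distributional identity: chi-square homogeneity between 1e4 draws of
  # each scheme, on aggregate cell counts and on the n11 distribution
  set.seed(66)
  one <- sapply(1:1e4, function(i) unclass(generate_table(50, p)))
  two <- sapply(1:1e4, function(i) unclass(generate_table_twostage(50, p)))
  agg <- rbind(rowSums(one), rowSums(two))
  expect_gt(chisq.test(agg)$p.value, 0.01)

  breaks <- c(-Inf, 5:14, Inf)
  h1 <- table(cut(one[1, ], breaks))
  h2 <- table(cut(two[1, ], breaks))
  expect_gt(chisq.test(rbind(h1, h2))$p.value, 0.01)
})

test_that("run_scenario estimates rejection probability with accounting", {
  # power regime: dS far below d0, large n -> near-certain rejection
  sc <- simulation_scenario(n = 5000, p01 = 0.05, p10 = 0.05, ds = 0.1,
                            d0 = 0.4444, n_sim = 2000, seed = 67)
  res <- run_scenario(sc)
  expect_gt(res$rejection_rate, 0.95)
  expect_equal(res$n_sim_effective, 2000L)
  expect_equal(res$mc_se,
               sqrt(res$rejection_rate * (1 - res$rejection_rate) / 2000))

  # alpha -> 0 kills every rejection
  sc0 <- simulation_scenario(n = 1000, p01 = 0.05, p10 = 0.05,
                             ds = 0.2857, d0 = 0.2857, alpha = 1e-12,
                             n_sim = 500, seed = 68)
  expect_equal(run_scenario(sc0)$rejection_rate, 0)

  # sparse scenarios discard undefined replicates and report it
  scs <- simulation_scenario(n = 60, p01 = 0.005, p10 = 0.005,
                             ds = 0.2857, d0 = 0.2857, n_sim = 2000,
                             seed = 69)
  ress <- run_scenario(scs)
  expect_lt(ress$n_sim_effective, 2000L)
  expect_gt(ress$n_sim_effective, 0L)
})

test_that("normal-test type-I inflation decreases with enrichment abundance", {
  lo <- run_scenario(simulation_scenario(
    n = 1000, p01 = 0.005, p10 = 0.005, ds = 1 / 3.5, d0 = 1 / 3.5,
    n_sim = 2e4, seed = 70))
  hi <- run_scenario(simulation_scenario(
    n = 1000, p01 = 0.2, p10 = 0.2, ds = 1 / 3.5, d0 = 1 / 3.5,
    n_sim = 2e4, seed = 71))
  expect_gt(lo$rejection_rate, hi$rejection_rate)
  expect_gt(hi$rejection_rate, 0.04)   # still close to the nominal level
})

test_that("bootstrap test is not more liberal than the normal one when sparse", {
  nrm <- run_scenario(simulation_scenario(
    n = 1000, p01 = 0.005, p10 = 0.005, ds = 1 / 3.5, d0 = 1 / 3.5,
    n_sim = 5000, seed = 72))
  bt <- run_scenario(simulation_scenario(
    n = 1000, p01 = 0.005, p10 = 0.005, ds = 1 / 3.5, d0 = 1 / 3.5,
    n_sim = 800, method = "bootstrap", B = 800, seed = 73))
  expect_lte(bt$rejection_rate,
             nrm$rejection_rate + 2 * (nrm$mc_se + bt$mc_se))
})

test_that("one-sided interval coverage is nominal in the asymptotic regime", {
  res <- run_scenario(simulation_scenario(
    n = 10000, p01 = 0.2, p10 = 0.2, p11 = 0.5,
    d0 = 0.2857, n_sim = 2e4, seed = 74))
  expect_lt(abs(res$coverage - 0.95), 3 * sqrt(0.95 * 0.05 / 2e4))
})

test_that("scenario construction validates and derives its quantities", {
  sc <- simulation_scenario(n = 1000, p01 = 0.05, p10 = 0.05,
                            ds = 0.2857, d0 = 0.2857)
  expect_equal(sc$p[["p11"]], (1 - 0.2857) * 0.1 / (2 * 0.2857))
  expect_equal(sc$dS_true, 0.2857, tolerance = 1e-12)
  expect_equal(sc$E_nu, 1000 * sum(unclass(sc$p)[1:3]))
  expect_error(simulation_scenario(n = 100, p01 = 0.1, p10 = 0.1,
                                   d0 = 0.5),
               class = "sorequiv_input_error")   # needs p11 or ds
  expect_error(simulation_scenario(n = 100, p01 = 0.1, p10 = 0.1,
                                   p11 = 0.2, ds = 0.5, d0 = 0.5),
               class = "sorequiv_input_error")
})

test_that("run_grid expands levels, reseeds deterministically and survives failures", {
  grid <- scenario_grid(d0 = c(0.2857, 0.3103, 0.4444, 0.4737),
                        n = c(500, 1000),
                        p_disc = cbind(p01 = c(0.005, 0.05),
                                       p10 = c(0.005, 0.05)),
                        n_sim = 300)
  expect_length(grid, 16)
  expect_setequal(round(unique(vapply(grid, `[[`, numeric(1), "d0")), 4),
                  c(0.2857, 0.3103, 0.4444, 0.4737))

  res1 <- run_grid(grid, seed = 75)
  res2 <- run_grid(grid, seed = 75)
  expect_identical(res1, res2)
  expect_equal(nrow(res1), 16)
  expect_true(all(res1$error == ""))
  expect_true(all(res1$mc_se > 0, na.rm = TRUE))

  # per-row failure containment: an unsimulatable scenario is reported,
  # the rest of the grid still runs
  broken <- simulation_scenario(n = 3, p01 = 0.001, p10 = 0.001,
                                ds = 0.2857, d0 = 0.2857, n_sim = 20,
                                seed = 76)
  res3 <- run_grid(c(grid[1], list(broken)), seed = 77)
  expect_equal(res3$error[1], "")
  expect_match(res3$error[2], "replicate")
  expect_true(is.na(res3$rejection_rate[2]))

  expect_error(run_grid(list()), class = "sorequiv_input_error")

  # CSV side-channel matches the returned frame
  f <- withr::local_tempfile(fileext = ".csv")
  run_grid(grid[1:2], seed = 78, out_csv = f)
  expect_equal(nrow(read.csv(f)), 2)
})

test_that("synth_gene_lists plants recoverable enrichment patterns", {
  fx <- synth_gene_lists(planted = c(5, 2, 2), seed = 79)
  expect_length(fx$lists, 2)
  expect_equal(colSums(unclass(fx$truth)), c(list1 = 7L, list2 = 7L))
  expect_identical(synth_gene_lists(planted = c(5, 2, 2), seed = 79)$lists,
                   fx$lists)

  # strong effect: the ORA front-end recovers the planted pattern for
  # nearly every seed
  hits <- vapply(1:100, function(s) {
    fx <- synth_gene_lists(planted = c(5, 2, 2), seed = s)
    prof <- profile_from_lists(fx$lists, fx$universe, fx$sets)
    identical(unclass(prof), unclass(fx$truth))
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # nothing planted: all-zero incidence, downstream undefined statistic
  fx0 <- synth_gene_lists(planted = c(0, 0, 0), seed = 80)
  prof0 <- profile_from_lists(fx0$lists, fx0$universe, fx0$sets)
  expect_error(sorensen_equiv_test(build_table(prof0, "list1", "list2"),
                                   d0 = 0.5),
               class = "sorequiv_undefined_statistic")

  expect_error(synth_gene_lists(n_genes = 100, n_terms = 20,
                                term_size = 40),
               class = "sorequiv_input_error")
  expect_error(synth_gene_lists(planted = c(30, 0, 0)),
               class = "sorequiv_input_error")
})
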