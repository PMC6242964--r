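test_that("Mann-Whitney U matches the textbook example and its symmetries", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method_detail, "exact")

  r_swap <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r_swap$p_value, r$p_value)
  expect_equal(r_swap$statistic, r$statistic)

  deg <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney equals full enumeration (tie-free, n = 3..5)", {
  for (n in 3:5) {
    vals <- withr::with_seed(n, rnorm(2 * n))
    splits <- utils::combn(2 * n, n)
    for (j in seq_len(ncol(splits))) {
      x <- vals[splits[, j]]
      y <- vals[-splits[, j]]
      expect_equal(mann_whitney_u(x, y)$p_value, enumerate_mw_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact and approximate p agree within 0.02 at n = 8", {
  x <- withr::with_seed(1, rnorm(8))
  y <- withr::with_seed(2, rnorm(8, 0.5))
  pe <- mann_whitney_u(x, y, mode = "exact")$p_value
  pa <- mann_whitney_u(x, y, mode = "approx")$p_value
  expect_lt(abs(pe - pa), 0.02)
})

test_that("Pearson chi-square matches the hand formula and its invariances", {
  even <- matrix(10, 2, 2)
  r <- chi_square_rxc(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  for (i in 1:100) {
    tab <- withr::with_seed(1000 + i,
      matrix(rpois(6, lambda = 20) + 1, sample(2:3, 1)))
    r <- chi_square_rxc(tab)
    expect_equal(r$statistic, hand_chi_square(tab), tolerance = 1e-12)
    perm <- tab[sample(nrow(tab)), sample(ncol(tab)), drop = FALSE]
    expect_equal(chi_square_rxc(perm)$statistic, r$statistic)
  }
  expect_error(chi_square_rxc(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chi_square_rxc(matrix(1:3, 1)), ">= 2 rows")
})

test_that("two-proportion comparisons reproduce published event-class tests", {
  eq <- chi_square_pairwise(20, 100, 10, 50)
  expect_equal(eq$p_value, 1)

  # full-decay prevalence: 38.26% of 149 vs 17.65% of 136
  k_wt <- reconstruct_counts(38.26, 149)
  k_hd <- reconstruct_counts(17.65, 136)
  expect_equal(k_wt$count, 57L)
  expect_equal(k_hd$count, 24L)
  p_fd <- chi_square_pairwise(k_wt$count, 149, k_hd$count, 136)$p_value
  expect_equal(signif(p_fd, 2), 0.00012)

  # decay-plateau prevalence: 36.24% vs 63.97%
  p_dp <- chi_square_pairwise(reconstruct_counts(36.24, 149)$count, 149,
                              reconstruct_counts(63.97, 136)$count,
                              136)$p_value
  expect_equal(signif(p_dp, 2), 2.9e-6)

  expect_error(chi_square_pairwise(11, 10, 1, 10), "0 <= k <= n")
})

test_that("count reconstruction rounds and reports residuals", {
  expect_equal(reconstruct_counts(0, 50)$count, 0L)
  expect_equal(reconstruct_counts(100, 50)$count, 50L)
  r <- reconstruct_counts(38.26, 149)
  expect_lt(r$residual_pct, 0.5)
  expect_warning(reconstruct_counts(10, 3), "inconsistent")
  expect_error(reconstruct_counts(101, 10), "percent")
})

test_that("both tests hold their nominal type-I error under the null", {
  reps <- 2000
  rej_mw <- withr::with_seed(77, mean(vapply(seq_len(reps), function(i) {
    mann_whitney_u(rnorm(20), rnorm(20), mode = "approx")$p_value < 0.05
  }, logical(1))))
  expect_gte(rej_mw, 0.035)
  expect_lte(rej_mw, 0.065)

  rej_chi <- withr::with_seed(78, mean(vapply(seq_len(reps), function(i) {
    k <- rbinom(2, 60, 0.4)
    chi_square_pairwise(k[1], 60, k[2], 60)$p_value < 0.05
  }, logical(1))))
  expect_gte(rej_chi, 0.035)
  expect_lte(rej_chi, 0.065)
})

test_that("experiment summaries assemble group stats and planned tests", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), const = rep(3, 4))
  rep1 <- summarize_experiment(g, comparisons = list(c("a", "a"),
                                                     c("a", "b")))
  expect_equal(rep1$summary$sem[rep1$summary$group == "const"], 0)
  expect_equal(rep1$tests$p_value[1], 1)   # a group against itself
  expect_equal(rep1$ecdfs$a(2.5), 0.5)
  expect_warning(summarize_experiment(list(a = 1:3, b = numeric(0))),
                 "empty")
  expect_error(summarize_experiment(g, comparisons = list(c("a", "zz"))),
               "unknown group")
})
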