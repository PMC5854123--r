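test_that("Monte-Carlo p-value is the unbiased (n+1)/(m+1) estimator", {
  expect_equal(round(mc_pvalue(73, 10000), 4), 0.0074)
  expect_equal(round(mc_pvalue(8245, 10000), 4), 0.8245)
  expect_equal(mc_pvalue(0, 1), 0.5)
  expect_equal(mc_pvalue(10, 10), 1)
  expect_error(mc_pvalue(-1, 10), "non-negative")
  expect_error(mc_pvalue(11, 10), "exceed")
  # monotone non-decreasing in the extreme count
  p <- vapply(0:100, mc_pvalue, 0, reps = 100)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("merge-rank binning correlates bin means", {
  set.seed(101)
  x <- runif(400)
  # identity: r = 1 at any binning
  r <- merge_rank_correlate(x, x, n_bins = 23)
  expect_equal(r$r, 1)
  expect_identical(nrow(r$bins), 23L)
  # bin sizes differ by at most one window
  sizes <- dronemap:::tabulate_sizes(400, 23)
  expect_lte(diff(range(sizes)), 1L)
  expect_identical(sum(sizes), 400L)
  # independent y: small |r| on bin means, raw Spearman near zero
  y <- runif(400)
  r2 <- merge_rank_correlate(x, y, n_bins = 23)
  expect_lt(abs(r2$raw_spearman), 0.15)
  # a monotone trend shows in both views
  y3 <- x + rnorm(400, 0, 0.3)
  r3 <- merge_rank_correlate(x, y3, n_bins = 23)
  expect_gt(r3$r, 0.9)
  expect_gt(r3$raw_spearman, 0.5)
  expect_warning(merge_rank_correlate(x, y3, n_bins = 10), "21-25")
  expect_error(merge_rank_correlate(x[1:10], y3[1:10], n_bins = 23),
               "fewer windows")
})

test_that("partial Spearman correlation matches its oracles", {
  set.seed(102)
  n <- 3000
  z <- rnorm(n)
  x <- 0.8 * z + rnorm(n)
  y <- -0.5 * z + rnorm(n)
  # x and y are conditionally independent given z: partial ~ 0 while the
  # marginal correlation is clearly negative
  expect_lt(abs(partial_spearman(x, y, z)), 0.06)
  expect_lt(cor(x, y, method = "spearman"), -0.15)
  # control independent of both: partial ~ plain Spearman
  w <- rnorm(n)
  expect_lt(abs(partial_spearman(x, y, w) -
                cor(x, y, method = "spearman")), 0.03)
  # closed-form oracle for a known trivariate structure:
  # partial = (rxy - rxz*ryz) / sqrt((1-rxz^2)(1-ryz^2))
  rxy <- cor(x, y, method = "spearman")
  rxz <- cor(x, z, method = "spearman")
  ryz <- cor(y, z, method = "spearman")
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_spearman(x, y, z), closed, tolerance = 1e-10)
  expect_error(partial_spearman(x, y, rep(1, n)), "constant")
  expect_error(partial_spearman(x, x, z), "degenerate|undefined")
})

test_that("dispersion test reproduces study variance and analytic null", {
  counts <- table2_counts()
  expect_identical(sum(counts), 23L)
  expect_equal(round(var(counts), 3), 0.789)
  res <- dispersion_test(counts, reps = 2000, seed = 7)
  expect_equal(res$observed, var(counts))
  expect_equal(res$p, mc_pvalue(res$n_extreme, 2000))
  expect_gt(res$p, 0.2)  # no over-dispersion signal at these counts
  # analytic multinomial oracle: E[sample variance] = total / n exactly
  expect_lt(abs(mean(res$null) - 23 / 32), 4 * sd(res$null) / sqrt(2000))
  # all-equal counts have zero variance, never exceeded downward
  res0 <- dispersion_test(rep(2L, 10), reps = 200, seed = 8)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)
  # identical seeds reproduce the full result
  expect_identical(dispersion_test(counts, reps = 500, seed = 9),
                   dispersion_test(counts, reps = 500, seed = 9))
})

test_that("colony heterogeneity chi-square on drone-count shares", {
  h <- colony_heterogeneity(c(17, 6), c(22, 10))
  expect_equal(round(h$expected, 2), c(15.81, 7.19))
  expect_identical(h$df, 1L)
  # brute-force cell summation oracle
  direct <- sum((c(17, 6) - h$expected)^2 / h$expected)
  expect_equal(h$statistic, direct)
  expect_gt(h$p, 0.05)
  expect_equal(colony_heterogeneity(c(10, 10), c(5, 5))$statistic, 0)
  expect_error(colony_heterogeneity(c(0, 0), c(5, 5)), "zero total")
})

test_that("proximity randomization counts same-drone breakpoint hits", {
  ev <- data.frame(drone = c("d1", "d2"), chrom = "LG1", kind = "CO",
                   start = c(99800, 5e5), end = c(99900, 5.001e5),
                   n_converted = 0L)
  lens <- c(LG1 = 1e6)
  # a mutation 146 bp from its own drone's crossover interval is proximal
  calls <- data.frame(drone = "d1", chrom = "LG1", pos = 99900 + 146)
  r <- proximity_test(calls, ev, lens, window_bp = 1000, reps = 200,
                      seed = 11)
  expect_identical(r$observed, 1L)
  # the same site against the other drone's events is not
  calls2 <- calls; calls2$drone <- "d2"
  r2 <- proximity_test(calls2, ev, lens, window_bp = 1000, reps = 200,
                       seed = 11)
  expect_identical(r2$observed, 0L)
  # pooled variant ignores drone identity
  r3 <- proximity_test(calls2, ev, lens, window_bp = 1000, reps = 200,
                       seed = 11, pooled = TRUE)
  expect_identical(r3$observed, 1L)
  # window 0: only sites inside the breakpoint interval count
  calls4 <- data.frame(drone = "d1", chrom = "LG1",
                       pos = c(99850, 99901))
  r4 <- proximity_test(calls4, ev, lens, window_bp = 0, reps = 200,
                       seed = 11)
  expect_identical(r4$observed, 1L)
  # analytic small-window oracle for the null proximal probability:
  # P ~ 1 - (1 - width/L)^k per mutation with k intervals of total
  # padded width
  set.seed(12)
  k <- 20
  ev5 <- data.frame(drone = "d1", chrom = "LG1", kind = "CO",
                    start = seq(2e4, by = 4.8e4, length.out = k),
                    end = seq(2e4, by = 4.8e4, length.out = k) + 100,
                    n_converted = 0L)
  calls5 <- data.frame(drone = rep("d1", 10), chrom = "LG1",
                       pos = seq(1e4, 9.9e5, length.out = 10))
  r5 <- proximity_test(calls5, ev5, lens, window_bp = 1000, reps = 3000,
                       seed = 13)
  p_site <- k * (100 + 2001) / 1e6
  expected_mean <- 10 * p_site
  expect_lt(abs(mean(r5$null) - expected_mean),
            4 * sd(r5$null) / sqrt(3000))
  expect_error(proximity_test(calls, ev[0, ], lens, reps = 200),
               "no crossover")
  expect_error(proximity_test(calls, ev, lens, reps = 10), "100")
})

test_that("conversion-direction bias test", {
  conv <- data.frame(from = c(rep("A", 23), rep("G", 13)),
                     to = c(rep("G", 23), rep("A", 13)))
  r <- conversion_bias_test(conv, reps = 5000, seed = 14)
  expect_identical(r$n_informative, 36L)
  expect_identical(r$n_to_gc, 23L)
  # exact binomial oracle: tail summation for 23 or more of 36 toward GC
  oracle <- sum(dbinom(23:36, 36, 0.5))
  expect_equal(r$binomial_p, oracle, tolerance = 1e-12)
  expect_equal(r$binomial_p, 0.066, tolerance = 0.01)
  # randomization p agrees with the binomial tail at these reps
  expect_lt(abs(r$p - (1 - pbinom(22, 36, 0.5))), 0.03)
  # uninformative conversions decline the test
  conv2 <- data.frame(from = c("A", "G"), to = c("T", "C"))
  expect_message(r2 <- conversion_bias_test(conv2), "declined")
  expect_null(r2)
})

test_that("rate-difference permutation test", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  r <- rate_difference_permutation(a, b, reps = 300, seed = 15)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)
  # null calibration: same-distribution groups rarely reject
  set.seed(16)
  pvals <- replicate(60, {
    x <- rpois(20, 4); y <- rpois(15, 4)
    rate_difference_permutation(x, y, reps = 99)$p
  })
  expect_lt(mean(pvals <= 0.05), 0.2)
  # a real shift is detected
  r2 <- rate_difference_permutation(rpois(30, 2), rpois(30, 9),
                                    reps = 999, seed = 17)
  expect_lt(r2$p, 0.01)
  expect_error(rate_difference_permutation(numeric(0), b), "non-empty")
})
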