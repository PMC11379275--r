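test_that("trimmed mean removes floor(trim*n) order statistics from each tail", {
  expect_equal(trimmed_mean(1:10, 0.2), 5.5)
  expect_equal(trimmed_mean(5, 0.2), 5)            # floor(0.2 * 1) = 0
  expect_equal(trimmed_mean(c(1, 2, 3, 4, 100), 0.2), 3)
  expect_equal(trimmed_mean(c(3, 1, 7), 0), mean(c(3, 1, 7)))
  expect_error(trimmed_mean(numeric(0)), "non-empty")
  expect_error(trimmed_mean(1:5, 0.5), "trim")
})

test_that("trimmed mean matches hand enumeration, is permutation-invariant and affine-equivariant", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(1:40, 1)
    x <- rnorm(n, sd = 5)
    trim <- runif(1, 0, 0.49)
    expect_equal(trimmed_mean(x, trim), oracle_trimmed_mean(x, trim))
    expect_equal(trimmed_mean(sample(x), trim), trimmed_mean(x, trim))
    a <- runif(1, -3, 3); b <- rnorm(1)
    expect_equal(trimmed_mean(a * x + b, trim),
                 a * trimmed_mean(x, trim) + b)
  }
})

test_that("winsorized variance replaces each tail by its boundary value", {
  x <- c(1, 2, 3, 4, 100)                 # g = 1: winsorize to 2,2,3,4,4
  expect_equal(winsorized_variance(x, 0.2), var(c(2, 2, 3, 4, 4)))
  expect_equal(winsorized_variance(x, 0), var(x))
})

test_that("one-way trimmed bootstrap test separates point masses and accepts identical groups", {
  g <- list(rep(0, 20), rep(10, 20))
  res <- bootstrap_oneway_trimmed(g, B = 599, seed = 3)
  expect_lte(res$p_value, 0.01)
  expect_gte(res$p_value, 1 / 600)        # never exactly zero

  same <- list(rep(2, 15), rep(2, 15))
  expect_equal(bootstrap_oneway_trimmed(same, B = 200, seed = 3)$p_value, 1)

  expect_error(bootstrap_oneway_trimmed(list(1:3), B = 599), ">= 2 groups")
  expect_error(bootstrap_oneway_trimmed(g, B = 50), "B must be")
  expect_error(bootstrap_oneway_trimmed(list(c(1, 2, 3), 1:20), trim = 0.4),
               "too small")
})

test_that("stochastic routines reproduce identical results for a fixed seed", {
  set.seed(99)
  g <- list(rnorm(25), rnorm(25, 0.5), rnorm(25, 1))
  r1 <- bootstrap_oneway_trimmed(g, B = 599, seed = 42)
  r2 <- bootstrap_oneway_trimmed(g, B = 599, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$statistic, r2$statistic)

  x <- runif(30); y <- 2 * x + rnorm(30, sd = 0.2)
  x2 <- runif(30); y2 <- 2 * x2 + rnorm(30, sd = 0.2)
  c1 <- compare_group_regressions(x, y, x2, y2, B = 300, seed = 7)
  c2 <- compare_group_regressions(x, y, x2, y2, B = 300, seed = 7)
  expect_identical(c1$slope_p, c2$slope_p)
  expect_identical(c1$intercept_p, c2$intercept_p)
})

test_that("explanatory effect size is zero for identical groups and grows with separation", {
  g0 <- list(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(explanatory_effect_size(g0), 0)
  set.seed(5)
  base <- replicate(3, rnorm(40), simplify = FALSE)
  shift1 <- base; shift1[[2]] <- shift1[[2]] + 1
  shift2 <- base; shift2[[2]] <- shift2[[2]] + 2
  expect_gt(explanatory_effect_size(shift2),
            explanatory_effect_size(shift1))
})

test_that("explanatory effect size is Monte-Carlo stable at large n", {
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    explanatory_effect_size(list(rnorm(1e4), rnorm(1e4, 1)))
  }, 0)
  expect_lt(sd(vals), 0.02)
})

test_that("Theil-Sen handles exact lines, symmetric scatter and tied x", {
  f <- theil_sen_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)

  f2 <- theil_sen_fit(c(0, 1, 2), c(0, 1, 0))   # pairwise slopes {1, 0, -1}
  expect_equal(f2$slope, 0)
  expect_equal(f2$intercept, 0)

  f3 <- theil_sen_fit(c(1, 1, 2), c(0, 10, 5))  # tied-x pair skipped
  o3 <- oracle_theil_sen(c(1, 1, 2), c(0, 10, 5))
  expect_equal(f3$slope, o3$slope)
  expect_equal(f3$intercept, o3$intercept)

  expect_error(theil_sen_fit(c(2, 2, 2), 1:3), "identical")
  expect_error(theil_sen_fit(1:3, 1:2), "equal length")
})

test_that("Theil-Sen is point-order invariant and affine-equivariant", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- 1.5 * x + rnorm(n)
    f <- theil_sen_fit(x, y)
    p <- sample(n)
    fp <- theil_sen_fit(x[p], y[p])
    expect_equal(fp$slope, f$slope)
    expect_equal(fp$intercept, f$intercept)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    fy <- theil_sen_fit(x, a * y + b)            # y-affine
    expect_equal(fy$slope, a * f$slope)
    expect_equal(fy$intercept, a * f$intercept + b)
    fx <- theil_sen_fit(a * x + b, y)            # x-affine
    expect_equal(fx$slope, f$slope / a)
  }
})

test_that("regression comparison flags well-separated slopes and recovers ln-ln generating slopes", {
  set.seed(13)
  x1 <- runif(50); y1 <- 2 * x1 + rnorm(50, sd = 0.1)
  x2 <- runif(50); y2 <- 3 * x2 + rnorm(50, sd = 0.1)
  cmp <- compare_group_regressions(x1, y1, x2, y2, B = 599, seed = 4)
  expect_lte(cmp$slope_p, 0.01)
  expect_true(cmp$slope_p >= 0 && cmp$intercept_p <= 1)

  # ln-ln synthetic ploidy groups: slopes recovered within 0.1
  set.seed(31)
  H <- runif(500, 30, 150)
  lnWd <- -11.7 + 2.74 * log(H) + rnorm(500, sd = 0.3)
  H2 <- runif(500, 30, 150)
  lnWt <- -11.4 + 2.58 * log(H2) + rnorm(500, sd = 0.3)
  fd <- theil_sen_fit(log(H), lnWd)
  ft <- theil_sen_fit(log(H2), lnWt)
  expect_lt(abs(fd$slope - 2.74), 0.1)
  expect_lt(abs(ft$slope - 2.58), 0.1)
})

test_that("slope-comparison bootstrap holds its type-I error under the null", {
  n_sim <- 200
  rej <- 0
  set.seed(2024)
  for (i in seq_len(n_sim)) {
    x1 <- runif(30); y1 <- 1 + 2 * x1 + rnorm(30, sd = 0.3)
    x2 <- runif(30); y2 <- 1 + 2 * x2 + rnorm(30, sd = 0.3)
    cmp <- compare_group_regressions(x1, y1, x2, y2, B = 200, seed = i)
    rej <- rej + (cmp$slope_p <= 0.05)
  }
  rate <- rej / n_sim
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-12)
})
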