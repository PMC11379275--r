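# The oracle for per-oyster nitrogen is direct evaluation of the printed
# constants (helper oracle_per_oyster_g), independent of the registry path.

test_that("per-oyster nitrogen combines dry-weight predictions with nutrient means", {
  per <- per_oyster_nitrogen(77)
  expect_equal(per$total_n_g, oracle_per_oyster_g(77), tolerance = 1e-12)
  expect_equal(per$tissue_n_g, 0.0905, tolerance = 1e-3)
  expect_equal(per$shell_n_g, 0.0546, tolerance = 1e-3)
  expect_equal(per$total_n_g, 0.1451, tolerance = 1e-3)
  expect_identical(per$total_n_g, per$tissue_n_g + per$shell_n_g)
  expect_equal(per_oyster_nitrogen(89)$total_n_g, 0.2114, tolerance = 1e-3)
  expect_error(per_oyster_nitrogen(-5), "positive")
})

test_that("zero nutrient concentrations give zero nitrogen", {
  reg <- default_registry()
  reg$nutrients$tissue$mean <- 1e-300   # effectively zero but inside range checks
  reg$nutrients$shell$mean <- 1e-300
  reg$nutrients$tissue$range <- c(0, 100)
  reg$nutrients$shell$range <- c(0, 100)
  expect_equal(per_oyster_nitrogen(77, reg)$total_n_g, 0, tolerance = 1e-290)
})

test_that("farm removal scales per-oyster nitrogen exactly and converts units coherently", {
  s1 <- harvest_scenario(1, 77, "mm")
  est1 <- farm_removal(s1)
  expect_identical(est1$farm_total_g, est1$per_oyster$total_n_g)

  s <- harvest_scenario(1e6, 89, "mm")
  est <- farm_removal(s)
  expect_identical(est$farm_total_g, est$per_oyster$total_n_g * 1e6)
  expect_identical(est$farm_total_kg, est$farm_total_g / 1000)
  expect_identical(est$farm_total_lb, est$farm_total_g / 453.59237)
  expect_lt(abs(est$farm_total_lb - 465) / 465, 0.05)

  est77 <- farm_removal(harvest_scenario(1e6, 77, "mm"))
  expect_lt(abs(est77$farm_total_lb - 311) / 311, 0.05)

  expect_error(harvest_scenario(0, 77), "positive integer")
  expect_error(harvest_scenario(10.5, 77), "positive integer")
})

test_that("removal is additive in count and strictly increasing in count and height", {
  for (H in c(64, 77, 89)) {
    g1 <- farm_removal(harvest_scenario(1200, H), band = FALSE)$farm_total_g
    g2 <- farm_removal(harvest_scenario(800, H), band = FALSE)$farm_total_g
    g3 <- farm_removal(harvest_scenario(2000, H), band = FALSE)$farm_total_g
    expect_identical(g1 + g2, g3)
  }
  totals_H <- vapply(c(64, 70, 77, 83, 89), function(H) {
    farm_removal(harvest_scenario(1000, H), band = FALSE)$farm_total_g
  }, 0)
  expect_true(all(diff(totals_H) > 0))
  totals_n <- vapply(c(10, 100, 1000), function(n) {
    farm_removal(harvest_scenario(n, 77), band = FALSE)$farm_total_g
  }, 0)
  expect_true(all(diff(totals_n) > 0))
})

test_that("period and farm metadata pass through without touching the numbers", {
  a <- farm_removal(harvest_scenario(5000, 77, period = "1 day",
                                     farm_name = "A", ploidy = "diploid"))
  b <- farm_removal(harvest_scenario(5000, 77, period = "5 years",
                                     farm_name = "B", practice = "no_gear"))
  expect_identical(a$farm_total_g, b$farm_total_g)
})

test_that("the interquartile band brackets the point estimate on the market span", {
  for (H in c(63.5, 77, 88.9)) {
    est <- farm_removal(harvest_scenario(1e6, H))
    expect_false(is.null(est$band_lb))
    expect_lte(est$band_lb[["lower"]], est$farm_total_lb)
    expect_gte(est$band_lb[["upper"]], est$farm_total_lb)
  }
})

test_that("a registry without band models yields a warned, band-free estimate", {
  reg <- default_registry()
  reg$models <- Filter(function(m) m$tau == 0.5, reg$models)
  s <- harvest_scenario(1e6, 77)
  expect_warning(b <- removal_band(s, reg), "band")
  expect_null(b)
  est <- farm_removal(s, reg)
  expect_null(est$band_lb)
  expect_gt(est$farm_total_lb, 0)
})

test_that("a degenerate band (both tau models equal the median model) collapses onto the point", {
  reg <- default_registry()
  mt <- registry_model(reg, "tissue")
  ms <- registry_model(reg, "shell")
  degen <- function(m, tau) { m$tau <- tau; m }
  reg$models <- list(mt, ms, degen(mt, 0.25), degen(mt, 0.75),
                     degen(ms, 0.25), degen(ms, 0.75))
  est <- farm_removal(harvest_scenario(1e6, 77), reg)
  expect_equal(est$band_lb[["lower"]], est$farm_total_lb)
  expect_equal(est$band_lb[["upper"]], est$farm_total_lb)
})

test_that("reverse calculation returns the ceiling count that covers the load", {
  per <- per_oyster_nitrogen(77)$total_n_g
  expect_identical(reverse_oyster_count(per, "g", 77, "mm"), 1)
  expect_identical(reverse_oyster_count(0.5 * per, "g", 77, "mm"), 1)
  n <- reverse_oyster_count(311, "lb", 77, "mm")
  expect_lt(abs(n - 1e6) / 1e6, 0.05)
  # forward-running the count covers the load; one fewer does not
  load_g <- mass_to_grams(311, "lb")
  expect_gte(farm_removal(harvest_scenario(n, 77), band = FALSE)$farm_total_g,
             load_g)
  expect_lt(farm_removal(harvest_scenario(n - 1, 77), band = FALSE)$farm_total_g,
            load_g)
  expect_error(reverse_oyster_count(0, "lb", 77, "mm"), "positive")
})

test_that("forward/reverse round trip is exact for the reference grid", {
  for (n in c(1, 10, 1e3, 1e6)) {
    for (H in c(64, 77, 89)) {
      est <- farm_removal(harvest_scenario(n, H), band = FALSE)
      expect_identical(reverse_oyster_count(est$farm_total_g, "g", H, "mm"), n)
    }
  }
})

test_that("subgroup models are a sensitivity switch, never the default", {
  s <- harvest_scenario(1e6, 77)
  overall <- farm_removal(s)
  dip <- farm_removal(s, model_group = "diploid")
  expect_false(isTRUE(all.equal(overall$farm_total_lb, dip$farm_total_lb)))
  expect_equal(dip$model_group, "diploid")
  expect_null(overall$model_group)
})

test_that("heights outside the documented window warn but still compute", {
  expect_warning(s <- harvest_scenario(100, 210, "mm"), "20-200 mm")
  expect_gt(farm_removal(s, band = FALSE)$farm_total_g, 0)
  expect_silent(harvest_scenario(100, 77, "mm"))
})
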