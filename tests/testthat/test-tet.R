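test_that("effective exposure adds food Tet and maternal carryover", {
  p <- tet_params()
  expect_equal(effective_exposure(0, 0, p), 0)
  # mothers at the 100 ug/ml fixed point, offspring Tet-free
  expect_equal(effective_exposure(0, 107.527, p), 7.52689, tolerance = 1e-5)
  # fixed point of E = 10 + 0.07 E
  expect_equal(effective_exposure(10, 10.753, p), 10.75271,
               tolerance = 1e-5)
  expect_error(effective_exposure(-1, 0), "non-negative")
  expect_error(effective_exposure(0, -5), "non-negative")
})

test_that("steady-state exposure equals the limit of the recursion", {
  p <- tet_params()
  iterate <- function(food, n = 200) {
    E <- 0
    for (i in seq_len(n)) E <- effective_exposure(food, E, p)
    E
  }
  for (food in c(0, 10, 100)) {
    expect_equal(rearing_steady_state(food, p), iterate(food),
                 tolerance = 1e-10)
  }
  expect_equal(rearing_steady_state(100, p), 107.5269, tolerance = 1e-4)
  expect_equal(rearing_steady_state(0, p), 0)
})

test_that("female survival follows the floored Hill curve", {
  p <- tet_params()
  expect_equal(female_survival(0, p), 0)
  # maternal carryover from a 10 ug/ml stock is below the lethality floor
  e <- effective_exposure(0, rearing_steady_state(10, p), p)
  expect_lt(e, p$e_floor)
  expect_equal(female_survival(e, p), 0)
  expect_equal(female_survival(107.527, p), 0.84736, tolerance = 1e-4)

  # monotone non-decreasing in E for random valid parameter sets
  set.seed(42)
  for (i in 1:20) {
    pp <- tet_params(kappa = runif(1, 0.01, 0.5),
                     e_floor = runif(1, 0.5, 4),
                     ec50 = runif(1, 4.5, 20),
                     hill_h = runif(1, 0.5, 5),
                     s_max = runif(1, 0.3, 1))
    grid <- seq(0, 200, length.out = 400)
    s <- female_survival(grid, pp)
    expect_true(all(diff(s) >= -1e-12))
    expect_true(all(s >= 0 & s <= pp$s_max))
  }
})

test_that("adult female fraction converts survival to sex ratio", {
  expect_equal(adult_female_fraction(1), 0.5)
  expect_equal(adult_female_fraction(0), 0)
  expect_equal(adult_female_fraction(0.520), 0.342, tolerance = 1e-3)
  s <- seq(0, 1, by = 0.01)
  expect_true(all(diff(adult_female_fraction(s)) > 0))
  expect_error(adult_female_fraction(1.2), "\\[0, 1\\]")
})

test_that("the calibration anchors are met", {
  rep <- check_anchors()
  expect_equal(rep$predicted, c(0.3933, 0.3420, 0, 0), tolerance = 1e-3)
  # anchors 3 and 4 are exactly zero under the lethality floor
  expect_identical(rep$predicted[3], 0)
  expect_identical(rep$predicted[4], 0)
  expect_true(all(abs(rep$residual) < 0.01))
})

test_that("maternal carryover delays lethality by exactly one generation at high Tet", {
  p <- tet_params()
  # lineage from a 100 ug/ml stock moved to Tet-free food
  E <- rearing_steady_state(100, p)
  f1 <- female_survival(effective_exposure(0, E, p), p)
  expect_gt(f1, 0); expect_lt(f1, 1)
  f2 <- female_survival(effective_exposure(0, effective_exposure(0, E, p), p), p)
  expect_identical(f2, 0)

  # lineages whose ancestors never exceeded 10 ug/ml stay at zero forever
  for (food in c(0, 2, 10)) {
    E <- rearing_steady_state(food, p)
    for (gen in 1:5) {
      E <- effective_exposure(0, E, p)
      expect_identical(female_survival(E, p), 0)
    }
  }
})

test_that("cohort simulation reproduces the analytic sex ratios", {
  set.seed(1)
  p <- tet_params()
  res <- simulate_sex_ratio(20000, rearing_steady_state(100, p), 0, p)
  expect_equal(res$adult_female_pct, 34.2, tolerance = 2)
  res <- simulate_sex_ratio(5000, rearing_steady_state(10, p), 0, p)
  expect_identical(res$n_female_adults, 0L)
  expect_equal(res$female_lethality_pct, 100)
})
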