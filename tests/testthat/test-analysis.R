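test_that("Hill fitting recovers exact and noisy dose-response curves", {
  d <- c(0, 1, 2, 5, 10, 20, 50, 100)
  y <- 1 * d^2 / (5^2 + d^2)
  f <- fit_hill(d, y)
  expect_equal(f$top, 1, tolerance = 1e-4)
  expect_equal(f$ec50, 5, tolerance = 1e-4)
  expect_equal(f$h, 2, tolerance = 1e-4)
  expect_equal(f$r_squared, 1, tolerance = 1e-8)
  expect_equal(unname(coef(f)), c(f$top, f$ec50, f$h))
  expect_equal(predict(f, 5), f$top / 2, tolerance = 1e-4)

  expect_error(fit_hill(d, rep(0, length(d))), "degenerate")
  expect_error(fit_hill(c(0, 1, 2), c(0, 1, 2)), "4 distinct")

  # parameter recovery from binomially noisy survival data generated by
  # the dosimetry model (above its lethality floor)
  set.seed(31)
  tp <- tet_params()
  doses <- c(3, 4, 6, 8, 12, 20, 40, 80, 150)
  n <- 200
  obs <- sapply(doses, function(d)
    stats::rbinom(1, n, female_survival(d, tp)) / n)
  f <- fit_hill(doses, obs)
  expect_lt(abs(f$ec50 - tp$ec50) / tp$ec50, 0.2)
})

test_that("a 1x1 sweep cell reproduces a direct season run", {
  temps <- synthesize_season(start = "2021-04-01", end = "2021-07-15",
                             seed = 3)
  cfg <- season_config(lifecycle = lifecycle_params(init_adults = 80))
  spec <- sweep_spec(strategies = "SSIMS_double_amp", sizes = 40,
                     intervals = 7, replicates = 1, seed_base = 3)
  sw <- run_sweep(spec, cfg, temps = temps)
  expect_equal(nrow(sw), 1L)

  cfg2 <- cfg
  cfg2$strategy <- release_strategy("SSIMS_double_amp", n = 40, interval = 7)
  direct <- run_season(cfg2, temps = temps, seed = sw$seed[1])
  expect_equal(sw$cumulative_wt[1],
               direct$cum_wt_hatched[length(direct$cum_wt_hatched)])
  expect_equal(sw$eradication_day[1], direct$eradication_day)
})

test_that("sweep output covers the full grid with recorded seeds", {
  temps <- synthesize_season(start = "2021-04-15", end = "2021-06-15",
                             seed = 2)
  cfg <- season_config(lifecycle = lifecycle_params(init_adults = 40))
  spec <- sweep_spec(strategies = c("RIDL", "SSIMS_male_only"),
                     sizes = c(0, 20), intervals = c(7, 25),
                     replicates = 2, seed_base = 2)
  sw <- run_sweep(spec, cfg, temps = temps)
  expect_equal(nrow(sw), 2 * 2 * 2 * 2)
  expect_false(any(duplicated(sw[c("strategy", "N", "F", "replicate")])))
  expect_true(all(!is.na(sw$seed)))
  sm <- summary(sw)
  expect_equal(nrow(sm), 8L)
  # an N = 0 cell is an untreated control: it matches a strategy-free
  # season run at the recorded seed
  z <- sw[sw$N == 0 & sw$F == 7 & sw$strategy == "RIDL" &
            sw$replicate == 1, ]
  untreated <- run_season(cfg, temps = temps, seed = z$seed)
  expect_equal(z$cumulative_wt,
               untreated$cum_wt_hatched[length(untreated$cum_wt_hatched)])
})

test_that("April-limited releases schedule four weekly events in April only", {
  temps <- synthesize_season(seed = 6)
  a <- april_limited_run("SSIMS_male_only", n = 80,
                         temps = temps, seeds = 6)
  tr <- a$traces[[1]]
  expect_equal(nrow(tr), nrow(temps))
  # no-release control: engineered count zero at both checkpoints
  ctl <- april_limited_run("none", n = 0, temps = temps, seeds = 6)
  expect_true(all(ctl$checkpoints$gm == 0))
  # checkpoints exist for June 1 and July 1
  expect_setequal(format(a$checkpoints$date),
                  c("2021-06-01", "2021-07-01"))
})
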