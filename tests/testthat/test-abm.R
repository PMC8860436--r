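test_that("sperm stores obey last-male precedence arithmetic", {
  s <- update_sperm_store(NULL, "A")
  expect_equal(s$weight, 1)
  s <- update_sperm_store(s, "B", p2 = 0.8)
  expect_equal(s$sire, c("A", "B"))
  expect_equal(s$weight, c(0.2, 0.8))
  s <- update_sperm_store(s, "C", p2 = 0.8)
  expect_equal(s$weight, c(0.04, 0.16, 0.8))
  expect_equal(sum(s$weight), 1)
  expect_error(update_sperm_store(NULL, "A", p2 = 1.5), "\\[0, 1\\]")
})

test_that("released cohorts have the strategy's composition and exposure", {
  tp <- tet_params()
  blk <- released_cohort(release_strategy("SSIMS_male_only", n = 10))
  expect_equal(length(blk$sex), 10L)
  expect_true(all(blk$sex == 2L))
  expect_true(all(blk$x1 == 2L & blk$pyr1 == 2L & blk$pta1 == 2L))
  expect_equal(unique(blk$E), rearing_steady_state(10, tp))

  blk <- released_cohort(release_strategy("RIDL", n = 10))
  expect_equal(sum(blk$sex == 1L), 5L)
  expect_true(all(blk$ridl1 == 2L & blk$ridl2 == 2L))

  blk <- released_cohort(release_strategy("SSIMS_double_amp", n = 0))
  expect_equal(length(blk$sex), 0L)
  expect_equal(unique(released_cohort(
    release_strategy("SSIMS_double_amp", n = 4))$E),
    rearing_steady_state(100, tp))

  expect_error(release_strategy("bogus"), "arg")
})

test_that("single-day dynamics honour the basic boundary cases", {
  cfg <- season_config()
  # empty state stays empty
  st <- new_season_state(cfg, init_adults = 0)
  set.seed(1)
  st <- step_day(st, 20, cfg)
  expect_equal(length(st$pop$sex), 0L)
  expect_equal(st$n_created, 0L)

  # one unmated female alone lays nothing
  st <- new_season_state(cfg, init_adults = 0)
  blk <- released_cohort(release_strategy("SSIMS_single_amp", n = 2))
  blk <- lapply(blk, function(v) v[1])        # keep only the female
  st$pop <- ssims:::.pop_bind(st$pop, blk)
  st$sperm <- vector("list", 1L)
  st$n_created <- 1L
  set.seed(2)
  for (d in 1:5) st <- step_day(st, 22, cfg)
  expect_equal(sum(st$pop$stage == 1L), 0L)
})

test_that("a female inseminated only by SSIMS males never produces larvae", {
  cfg <- season_config()
  st <- new_season_state(cfg, init_adults = 0)
  # one wild female whose store is 100% SSIMS sires
  fem <- ssims:::.cohort_block("WT", 2, 1, E = 0, origin = 1L,
                               tp = cfg$tet)
  fem <- lapply(fem, function(v) v[1])
  st$pop <- ssims:::.pop_bind(st$pop, fem)
  st$sperm <- list(list(w = 1, g = matrix(c(2L, 2L, 2L, 2L, 2L, 1L, 1L),
                                          nrow = 1L)))
  st$n_created <- 1L
  set.seed(3)
  eggs_seen <- 0L
  for (d in 1:30) {
    st <- step_day(st, 22, cfg)
    eggs_seen <- eggs_seen + sum(st$pop$stage == 1L)
    expect_equal(sum(st$pop$stage >= 2L & st$pop$origin == 3L), 0L)
  }
  expect_gt(eggs_seen, 0L)  # she lays, but nothing ever hatches
})

test_that("eradication day is the first day of a persistent zero", {
  expect_equal(days_to_eradication(c(5, 2, 0, 0)), 3L)
  expect_equal(days_to_eradication(c(1, 0, 3, 0, 0)), 4L)
  expect_true(is.na(days_to_eradication(c(5, 2, 1, 1))))
  expect_equal(days_to_eradication(c(0, 0, 0)), 1L)
})

test_that("season runs conserve individuals and expose a coherent summary", {
  cfg <- season_config(lifecycle = lifecycle_params(init_adults = 60))
  temps <- synthesize_season(start = "2021-04-01", end = "2021-07-01",
                             seed = 11)
  s <- run_season(cfg, temps = temps, seed = 11)
  expect_s3_class(s, "season_summary")
  expect_equal(s$conservation$created - s$conservation$deaths,
               s$conservation$alive)
  expect_true(all(diff(s$cum_wt_hatched) >= 0))
  expect_true(all(s$counts >= 0))
  expect_equal(dim(s$counts), c(nrow(temps), 6L, 2L, 4L, 3L))
  df <- as.data.frame(s)
  expect_true(all(df$count > 0))
  expect_equal(sum(df$count[df$day == 10]), s$total[10])

  # a zero-population, no-release run is an all-zero trace
  s0 <- run_season(season_config(lifecycle = lifecycle_params(init_adults = 0)),
                   temps = temps, seed = 1)
  expect_true(all(s0$total == 0))
  expect_equal(s0$cum_wt_hatched[nrow(temps)], 0L)

  # release window must lie inside the series
  bad <- season_config(strategy = release_strategy(
    "RIDL", n = 10, interval = 7,
    window = c("2021-01-01", "2021-02-01")))
  expect_error(run_season(bad, temps = temps, seed = 1), "window")
})

test_that("identical seed and configuration give bit-identical seasons", {
  cfg <- season_config(
    lifecycle = lifecycle_params(init_adults = 80),
    strategy = release_strategy("SSIMS_double_amp", n = 20, interval = 14))
  temps <- synthesize_season(start = "2021-04-01", end = "2021-07-15",
                             seed = 5)
  a <- run_season(cfg, temps = temps, seed = 5)
  b <- run_season(cfg, temps = temps, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cum_wt_hatched, b$cum_wt_hatched)
  expect_identical(a$eradication_day, b$eradication_day)
  c <- run_season(cfg, temps = temps, seed = 6)
  expect_false(identical(a$counts, c$counts))
})
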