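test_that("fecundity assay reflects the sperm-store composition", {
  wt <- format(strain_genotype("WT", "male"))
  ssims <- format(strain_genotype("SSIMS", "male"))

  # 100% SSIMS store: every egg is an inviable hybrid
  set.seed(1)
  for (i in 1:10)
    expect_identical(
      fecundity_assay(data.frame(sire = ssims, weight = 1)), 0L)

  # unmated female: nothing to fertilise
  expect_identical(fecundity_assay(NULL), 0L)

  # 100% WT store: counts centred on the calibrated per-vial mean
  set.seed(2)
  wt_counts <- replicate(200, fecundity_assay(
    data.frame(sire = wt, weight = 1)))
  expect_equal(mean(wt_counts), 75, tolerance = 0.05)

  # mixed store: expectation scales with the wild-type weight
  set.seed(3)
  mixed <- replicate(300, fecundity_assay(
    data.frame(sire = c(wt, ssims), weight = c(0.2, 0.8))))
  expect_equal(mean(mixed), 0.2 * 75, tolerance = 0.1)

  expect_error(fecundity_assay(data.frame(sire = wt, weight = 1),
                               mother = strain_genotype("WT", "male")),
               "female")
})

test_that("a single-week cage with no releases is just the seeded adults", {
  ct <- run_cage(cage_config(weeks = 1, release_size = 0, init_wt = 200),
                 seed = 4)
  expect_equal(ct$weeks, 1L)
  # only wild type ever present
  expect_equal(sum(ct$trap[, -1L, ]), 0L)
  expect_equal(sum(ct$census[, -1L, ]), 0L)
  # census after one week: initial minus trapping and a week of mortality
  total <- sum(ct$census[1, "WT", ])
  expect_lt(total, 200)
  expect_gt(total, 200 * (1 - 1 / 3 - 0.25))
})

test_that("an untreated cage rises to a plateau with no engineered flies", {
  ct <- run_cage(cage_config(release_size = 0), seed = 9)
  wt <- rowSums(ct$trap[, "WT", ])
  expect_equal(sum(ct$trap[, -1L, ]), 0L)
  # gradual rise, then a plateau from about week 6
  expect_gt(mean(wt[6:16]), mean(wt[1:3]))
  late <- wt[6:16]
  expect_lt(stats::sd(late) / mean(late), 0.25)
  # the fecundity assay sees fully fertile wild-type females
  expect_gt(mean(unlist(ct$fecundity[6:10])), 50)
})

test_that("cage runs are reproducible under a fixed seed", {
  a <- run_cage(cage_config(weeks = 5), seed = 12)
  b <- run_cage(cage_config(weeks = 5), seed = 12)
  expect_identical(a$trap, b$trap)
  expect_identical(a$census, b$census)
  expect_identical(a$fecundity, b$fecundity)
})
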