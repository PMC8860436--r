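test_that("gamete enumeration matches Mendelian expectation", {
  # hemizygous X, homozygous autosomes: two gametes at 1/2 each
  g <- enumerate_gametes(strain_genotype("SSIMS", "male"))
  expect_equal(nrow(g), 2L)
  expect_setequal(g$x, c("FL", "Y"))
  expect_equal(g$prob, c(0.5, 0.5))
  expect_true(all(g$pyr == "res" & g$pta == "PTA" & g$ridl == "+"))

  # fully homozygous female: a single certain gamete
  g <- enumerate_gametes(strain_genotype("WT", "female"))
  expect_equal(nrow(g), 1L)
  expect_equal(g$prob, 1)
  expect_equal(unname(unlist(g[1, c("x", "pyr", "pta", "ridl")])),
               c("+", "wt", "+", "+"))

  # triple heterozygote: 2^3 = 8 gametes at 1/8 each
  het <- genotype("XX", c("+", "FL"), c("res", "wt"), c("PTA", "+"),
                  c("+", "+"))
  g <- enumerate_gametes(het)
  expect_equal(nrow(g), 8L)
  expect_equal(g$prob, rep(0.125, 8))
  expect_equal(nrow(unique(g[c("x", "pyr", "pta", "ridl")])), 8L)
})

test_that("gamete probabilities sum to 1 for every constructible genotype", {
  for (g in all_genotypes()) {
    gam <- enumerate_gametes(g)
    expect_equal(sum(gam$prob), 1)
    if (g$karyotype == "XX") expect_false(any(gam$x == "Y"))
    else expect_equal(sum(gam$prob[gam$x == "Y"]), 0.5)
  }
})

test_that("fertilization unions parental alleles and sets karyotype", {
  egg <- list(x = "+", pyr = "wt", pta = "+", ridl = "+")
  sperm_y <- list(x = "Y", pyr = "res", pta = "PTA", ridl = "+")
  z <- fertilize(egg, sperm_y)
  expect_equal(z$karyotype, "XY")
  expect_setequal(z$pyr, c("wt", "res"))
  expect_setequal(z$pta, c("+", "PTA"))

  egg_s <- list(x = "FL", pyr = "res", pta = "PTA", ridl = "+")
  z <- fertilize(egg_s, egg_s)  # SSIMS x SSIMS gametes
  expect_equal(classify(z), "SSIMS")
  expect_equal(sex_of(z), "female")

  # any Y-bearing sperm makes a male
  z <- fertilize(egg_s, sperm_y)
  expect_equal(z$karyotype, "XY")

  expect_error(fertilize(sperm_y, egg), "Y")
})

test_that("EGI viability follows the haplosufficient-PTA rule", {
  # hybrid: one PTA copy, one wild-type promoter -> dead
  expect_false(egi_viable(genotype("XY", "+", c("res", "wt"),
                                   c("PTA", "+"))))
  # no PTA at all -> alive
  expect_true(egi_viable(strain_genotype("WT", "male")))
  # true-breeding engineered line -> alive
  expect_true(egi_viable(strain_genotype("SSIMS", "female")))

  # brute-force oracle over all 9 pta-pair x pyr-pair combinations
  pairs <- function(a) list(c(a[1], a[1]), c(a[1], a[2]), c(a[2], a[2]))
  for (pta in pairs(c("PTA", "+"))) for (pyr in pairs(c("res", "wt"))) {
    g <- genotype("XX", c("+", "+"), pyr, pta)
    expect_identical(egi_viable(g), oracle_egi(g))
  }
})

test_that("RIDL lethality is dominant and Tet-repressible", {
  het <- genotype("XY", "+", ridl = c("RIDL", "+"))
  hom <- genotype("XX", c("+", "+"), ridl = c("RIDL", "RIDL"))
  expect_false(ridl_viable(het, food_tet = 0))
  expect_true(ridl_viable(strain_genotype("WT", "male"), 0))
  expect_true(ridl_viable(hom, food_tet = 100))
  expect_error(ridl_viable(het, -1), "non-negative")
})

test_that("classification assigns the documented strain labels", {
  expect_equal(classify(strain_genotype("WT", "female")), "WT")
  expect_equal(classify(strain_genotype("SSIMS", "male")), "SSIMS")
  expect_equal(classify(strain_genotype("EGI", "female")), "EGI")
  expect_equal(classify(strain_genotype("FL", "male")), "FL")
  expect_equal(classify(strain_genotype("RIDL", "female")), "RIDL")
  hybrid <- genotype("XY", "+", c("res", "wt"), c("PTA", "+"))
  expect_equal(classify(hybrid), "OTHER")
  expect_equal(sex_of(strain_genotype("WT", "female")), "female")
  expect_equal(sex_of(strain_genotype("SSIMS", "male")), "male")
})

test_that("cross distributions reproduce the incompatibility outcomes", {
  wt_f <- strain_genotype("WT", "female")
  ssims_m <- strain_genotype("SSIMS", "male")
  cd <- cross_distribution(wt_f, ssims_m)
  expect_equal(sum(cd$probability), 1)
  # every hybrid inherits one PTA and one resistance copy; none viable
  expect_equal(sum(cd$probability[!cd$egi_viable]), 1)
  for (code in cd$genotype) {
    z <- parse_genotype(code)
    expect_setequal(z$pta, c("PTA", "+"))
    expect_setequal(z$pyr, c("res", "wt"))
  }

  cd <- cross_distribution(wt_f, strain_genotype("WT", "male"))
  expect_equal(nrow(cd), 2L)  # XX and XY wild type
  expect_true(all(cd$egi_viable))
  expect_true(all(vapply(cd$genotype,
                         function(c) classify(parse_genotype(c)) == "WT",
                         logical(1))))

  cd <- cross_distribution(strain_genotype("SSIMS", "female"), ssims_m)
  expect_true(all(cd$egi_viable))
  expect_true(all(vapply(cd$genotype,
                         function(c) classify(parse_genotype(c)) == "SSIMS",
                         logical(1))))

  expect_error(cross_distribution(ssims_m, ssims_m), "XX mother")
})

test_that("cross_distribution equals the brute-force oracle on all strain pairs", {
  for (ms in strain_templates) for (fs in strain_templates) {
    mother <- strain_genotype(ms, "female")
    father <- strain_genotype(fs, "male")
    got <- cross_distribution(mother, father)
    got <- got[order(got$genotype), ]
    want <- oracle_cross(mother, father)
    expect_equal(got$genotype, want$genotype,
                 info = paste(ms, "x", fs))
    expect_equal(got$probability, want$probability, tolerance = 1e-12,
                 info = paste(ms, "x", fs))
  }
})

test_that("X-linkage law holds: sons never, daughters always inherit the paternal X", {
  # use an FL-marked father so the paternal X is identifiable
  for (ms in strain_templates) {
    mother <- strain_genotype(ms, "female")
    father <- strain_genotype("FL", "male")   # X carries FL
    cd <- cross_distribution(mother, father)
    for (code in cd$genotype) {
      z <- parse_genotype(code)
      if (z$karyotype == "XY") {
        # a son's X comes from the mother
        expect_true(z$x %in% mother$x)
        if (ms %in% c("WT", "EGI", "RIDL")) expect_equal(z$x, "+")
      } else {
        expect_true("FL" %in% z$x)
      }
    }
  }
})

test_that("genotype string codes round-trip losslessly", {
  for (g in all_genotypes()) {
    code <- format(g)
    expect_identical(format(parse_genotype(code)), code)
  }
  expect_equal(format(strain_genotype("SSIMS", "male")),
               "XFL/Y;res,res;PTA,PTA;+,+")
  expect_error(parse_genotype("XFL/Y;res,res"), "malformed")
  expect_error(genotype("XY", c("+", "+")), "exactly 1")
  expect_error(genotype("XX", c("+", "+"), pyr = c("bogus", "wt")), "pyr")
})
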