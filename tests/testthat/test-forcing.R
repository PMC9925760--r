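test_that("the lethal curve has its logistic identities", {
  r <- mortality_response(c = 1e5, b = 2)
  expect_equal(mortality_proportion(1e5, r), 0.5)
  expect_equal(mortality_proportion(0, r), 0)
  # direct evaluation: (1e6/1e5)^-2 = 1e-2 -> 1/(1 + 1e-2)
  expect_equal(mortality_proportion(1e6, r), 1 / 1.01, tolerance = 1e-12)
  # monotone in x; clipped below 1
  x <- 10^seq(2, 9, by = 0.25)
  a <- mortality_proportion(x, r)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a < 1))
})

test_that("smaller inflections dominate at equal slope", {
  x <- 10^seq(3, 8, by = 0.5)
  a_lo <- mortality_proportion(x, mortality_response(1e4, 2))
  a_hi <- mortality_proportion(x, mortality_response(1e6, 2))
  expect_true(all(a_lo > a_hi))
})

test_that("annualization is the exact monthly-rate inverse", {
  expect_equal(annualize(0), 0)
  expect_equal(annualize(0.5), 12 * log(2))
  A <- seq(0.1, 0.9, by = 0.1)
  expect_equal(exp(-annualize(A) / 12), 1 - A, tolerance = 1e-15)
  expect_equal(1 - exp(-annualize(A) / 12), A, tolerance = 1e-15)
  expect_error(annualize(1), "clip")
})

test_that("the other-mortality multiplier scales as a ratio", {
  expect_equal(m0_multiplier(0.4, 0.4)$mult, 1)
  expect_equal(m0_multiplier(0, 0.7)$mult, 0)
  expect_equal(m0_multiplier(12 * log(2), 0.4)$mult, 12 * log(2) / 0.4)
  expect_equal(m0_multiplier(12 * log(2), 0.4)$mult, 20.79, tolerance = 1e-3)
  # EE = 1 groups have no baseline other mortality to scale against
  z <- m0_multiplier(2, 0)
  expect_true(z$direct)
  expect_equal(z$absolute, 2)
})

test_that("foraging curves halve at their inflection and translate", {
  f <- foraging_response(5e4)
  expect_equal(foraging_multiplier(5e4, f), 0.5)
  x <- seq(0, 5e5, length.out = 100)
  expect_true(all(diff(foraging_multiplier(x, f)) <= 0))
  # translation invariance of shape: shifting x by the inflection offset
  # maps one curve onto another
  f2 <- foraging_response(2e5)
  expect_equal(foraging_multiplier(x, f),
               foraging_multiplier(x + (2e5 - 5e4), f2))
})

test_that("response libraries have the printed cardinalities", {
  m <- build_mortality_library()
  f <- build_foraging_library(m)
  expect_equal(nrow(m), 20)
  expect_equal(nrow(f), 15)
  expect_equal(length(unique(m$c)), 5)
  expect_equal(length(unique(m$b)), 4)
  # each inflection appears in exactly 4 mortality curves
  expect_true(all(table(m$c) == 4))
  # three foraging fractions per inflection level, placed below it
  expect_true(all(table(f$sensitivity) == 3))
  expect_equal(sort(unique(f$fraction)), c(0.25, 0.5, 0.75))
  expect_true(all(f$inflection < max(m$c)))
  # paired construction: fraction 0.5 of a 1e5 inflection sits at 5e4
  m2 <- build_mortality_library(inflections = 1e5, slopes = 1:4)
  f2 <- build_foraging_library(m2)
  expect_equal(f2$inflection[f2$fraction == 0.5], 5e4)
})

test_that("the scenario grid crosses to exactly 160 members", {
  sc <- build_scenario_grid(target_group = "grouper")
  expect_equal(nrow(sc), 160)
  expect_equal(sum(sc$target == "all_consumers"), 80)
  expect_equal(sum(is.na(sc$foraging_curve)), 2 * 20)
  expect_equal(sum(!is.na(sc$foraging_curve) & sc$target == "all_consumers"),
               60)
  expect_equal(anyDuplicated(sc$scenario), 0)
  # foraging curves are paired to their mortality curve's inflection level
  both <- sc[!is.na(sc$foraging_curve), ]
  expect_equal(both$inflection, both$fraction * both$c)
})

test_that("forcing is the identity off-target and at zero concentration", {
  sc <- build_scenario_grid(target_group = "grouper")
  scen <- sc[sc$target == "single", ][1, ]
  out <- apply_forcing(B = 2, x = 1e6, scenario = scen, group = "mackerel",
                       is_consumer = TRUE, m0base = 0.4)
  expect_equal(out, list(loss = 0, m0mult = 0, foraging = 1))
  out0 <- apply_forcing(B = 2, x = 0, scenario = scen, group = "grouper",
                        is_consumer = TRUE, m0base = 0.4)
  expect_equal(out0$loss, 0)
  # A = 0.25 at x = c/3 with slope 1: loss = 0.25 * 2 = 0.5
  scen2 <- scen
  scen2$b <- 1
  out2 <- apply_forcing(B = 2, x = scen2$c / 3, scenario = scen2,
                        group = "grouper", is_consumer = TRUE, m0base = 0.4)
  expect_equal(out2$loss, 0.5)
  expect_equal(out2$m0mult, annualize(0.25) / 0.4)
})
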