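# minimal hand-built trajectory: 2 water cells, 24 months, 3 groups
fake_run <- function(B_fill = 1, loss_fill = 0) {
  groups <- tibble::tibble(
    group = c("a", "b", "det"),
    type = c("consumer", "consumer", "detritus"),
    trait = c("demersal", "upper TL pelagic", "detritus"),
    taxon = c("fishes", "elasmobranchs", "detritus"),
    harvested = c(TRUE, FALSE, FALSE),
    juvenile = FALSE
  )
  arr <- function(x) array(x, c(24, 2, 3),
                           dimnames = list(NULL, NULL, groups$group))
  structure(
    list(B = arr(B_fill), loss = arr(loss_fill), catch = arr(0),
         groups = groups, scenario = "fake", n_months = 24),
    class = "rt_run"
  )
}

test_that("ecosystem indicators match hand arithmetic", {
  run <- fake_run(B_fill = 1)
  run$B[, , "det"] <- 5           # detritus never counts
  run$catch[, , "a"] <- 0.02      # per month
  run$loss[13, , "b"] <- 0.25     # one month of loss in year 2
  ind <- ecosystem_indicators(run)
  expect_s3_class(ind, "rt_indicators")
  expect_equal(ind$year, 1:2)
  expect_equal(ind$B_T, c(2, 2))          # two living groups of 1
  expect_equal(ind$B_har, c(1, 1))        # only "a" is harvested
  expect_equal(ind$C_T, c(0.24, 0.24))    # 12 x 0.02
  expect_equal(ind$B_loss, c(0, 0.25))
  # indicator linearity: a two-group split sums to the total
  runA <- run; runA$B[, , "b"] <- 0
  runB <- run; runB$B[, , "a"] <- 0
  expect_equal(ecosystem_indicators(runA)$B_T +
                 ecosystem_indicators(runB)$B_T, ind$B_T)
})

test_that("the mortality index is the loss over mean standing stock", {
  run <- fake_run(B_fill = 1)
  expect_equal(mortality_index(run, "a")$rate, c(0, 0))
  # single month with a 10% kill everywhere: rate = 0.1 exactly
  run$loss[7, , "a"] <- 0.1
  mi <- mortality_index(run, "a")
  expect_equal(mi$rate[1], 0.1)
  expect_equal(mi$rate[2], 0)
  # ratio is homogeneous: doubling both fields leaves it unchanged
  run2 <- run
  run2$B <- 2 * run$B; run2$loss <- 2 * run$loss
  expect_equal(mortality_index(run2, "a")$rate, mi$rate)
  expect_error(mortality_index(run, "zzz"), "unknown group")
})

test_that("community aggregates sum their members and drop juveniles", {
  run <- fake_run(B_fill = 1)
  run$B[, , "b"] <- 3
  ag <- community_aggregate(run, by = "trait")
  expect_equal(ag$biomass[ag$class == "demersal"], c(1, 1))
  expect_equal(ag$biomass[ag$class == "upper TL pelagic"], c(3, 3))
  # one class holding every group equals B_T plus the detritus pool
  all_map <- setNames(rep("all", 3), c("a", "b", "det"))
  run2 <- fake_run(B_fill = 1)
  ag2 <- community_aggregate(run2, by = all_map)
  expect_equal(ag2$biomass[ag2$class == "all"],
               ecosystem_indicators(run2)$B_T + 1)  # det biomass of 1
  # juvenile groups are excluded
  run3 <- fake_run(B_fill = 1)
  run3$groups$juvenile[2] <- TRUE
  ag3 <- community_aggregate(run3, by = "trait")
  expect_false("upper TL pelagic" %in% ag3$class)
})

test_that("scenario screening equals the brute-force filter", {
  withr::with_seed(7, {
    runs <- tibble::tibble(
      scenario = sprintf("s%03d", 1:200),
      rate = runif(200, 0, 2),
      rmse = runif(200, 0.1, 0.115)   # clustered, so several pass the filter
    )
  })
  acc <- screen_scenarios(runs, mu = 0.77, sigma = 0.12)
  brute <- runs[abs(runs$rate - 0.77) <= 2 * 0.12 &
                  runs$rmse <= 1.10 * min(runs$rmse), ]
  expect_equal(acc$scenario, brute$scenario)
  # idempotent and order-independent
  expect_equal(screen_scenarios(acc)$scenario, acc$scenario)
  shuf <- withr::with_seed(8, runs[sample(200), ])
  expect_equal(sort(screen_scenarios(shuf)$scenario), sort(acc$scenario))
  # band edges
  one <- tibble::tibble(scenario = c("x", "y"),
                        rate = c(0.77, 0.77 + 3 * 0.12),
                        rmse = c(0.5, 0.5))
  expect_equal(screen_scenarios(one)$scenario, "x")
  expect_error(screen_scenarios(one[0, ]), "empty")
})

test_that("log-scale RMSE scores shape, not scale", {
  obs <- c(1, 2, 3, 5, 2)
  expect_equal(index_rmse(10 * obs, obs), 0)
  expect_gt(index_rmse(rev(obs), obs), 0)
})

test_that("stratified comparisons recover imposed contrasts", {
  run <- fake_run(B_fill = 2)
  both <- list(before = list(cells = 1:2, timestep = 3),
               after = list(cells = 1:2, timestep = 20))
  out <- before_after_in_out(run, c("a", "b"), both)
  expect_equal(out$pct_change[2], 0)       # identical strata
  expect_equal(out$mean, c(4, 4))
  expect_equal(out$se, c(0, 0))            # constant field
  # a 50% kill in the "after" stratum
  run$B[20, , c("a", "b")] <- 1
  out2 <- before_after_in_out(run, c("a", "b"), both)
  expect_equal(out2$pct_change[2], -50)
  expect_error(
    before_after_in_out(run, "a", list(x = list(cells = integer(), timestep = 1),
                                       y = list(cells = 1, timestep = 1))),
    "empty stratum")
})

test_that("a simulated half-kill shows up as ~-50% inside the bloom", {
  # slow-rate web so one month of dynamics barely moves the field
  m <- calibrate_model(slow_web(), dispersal_mult = 0)
  g <- grid5()
  S <- n_water(g)
  b <- zero_blooms(g, 1)
  inside <- 1:8
  b$x[1, inside] <- 1e5
  sc <- build_scenario_grid(target_group = "grazer")
  scen <- sc[sc$target == "all_consumers" & is.na(sc$foraging_curve), ][1, ]
  scen$c <- 1e5; scen$b <- 2    # A = 0.5 at the imposed concentration
  run <- run_simulation(m, g, blooms = b, scenario = scen, n_months = 1,
                        spinup_months = 0)
  cmp <- before_after_in_out(
    run, "grazer",
    list(outside = list(cells = setdiff(1:S, inside), timestep = 1),
         inside = list(cells = inside, timestep = 1))
  )
  expect_equal(cmp$pct_change[2], -50, tolerance = 0.01)
})
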