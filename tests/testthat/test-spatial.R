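test_that("habitat capacity is a floored product of responses", {
  expect_equal(habitat_capacity(c(sst = 25), list(), c(sst = 25)), 1)
  # the sublethal multiplier enters the product directly
  expect_equal(habitat_capacity(c(sst = 25), list(), c(sst = 25),
                                foraging = 0.4), 0.4)
  # a zero response floors at eps rather than annihilating the cell
  expect_equal(habitat_capacity(c(sst = 25), list(), c(sst = 25),
                                foraging = 0), 1e-4)
  # normalisation: suitability is 1 at the baseline driver value and
  # drops below 1 away from it (for an increasing preference)
  r <- list(list(var = "sst", mid = 16, scale = 3, direction = 1))
  expect_equal(habitat_capacity(c(sst = 25), r, c(sst = 25)), 1)
  expect_lt(habitat_capacity(c(sst = 18), r, c(sst = 25)), 1)
  # two responses multiply
  r2 <- c(r, list(list(var = "sbt", mid = 16, scale = 3, direction = 1)))
  one <- habitat_capacity(c(sst = 18, sbt = 25), r2, c(sst = 25, sbt = 25))
  expect_equal(one, habitat_capacity(c(sst = 18), r, c(sst = 25)))
})

test_that("movement conserves mass and is neutral under symmetry", {
  g <- grid5()
  S <- n_water(g)
  # uniform biomass, uniform capacity: nothing moves
  B <- rep(2.5, S)
  expect_equal(movement_step(B, rep(0.7, S), 300, g), B)
  # random fields conserve the domain total to near machine precision
  withr::with_seed(2, {
    for (k in 1:20) {
      B <- runif(S, 0, 10)
      cap <- runif(S, 1e-4, 1)
      B2 <- movement_step(B, cap, 300, g)
      expect_lt(abs(sum(B2) - sum(B)), 1e-12 * sum(B))
      expect_true(all(B2 >= 0))
    }
  })
})

test_that("biomass drains toward the better of two connected cells", {
  mask <- matrix(TRUE, 2, 2)
  mask[1, 1] <- FALSE
  mask[1, 2] <- FALSE      # two water cells side by side
  g2 <- make_grid(2, 2, 10, land = mask)
  B <- c(1, 1)
  cap <- c(1, 1e-4)
  for (k in 1:20) {
    B_new <- movement_step(B, cap, 300, g2)
    expect_gte(B_new[1], B[1])       # good cell accumulates monotonically
    expect_equal(sum(B_new), 2)
    B <- B_new
  }
  expect_gt(B[1], 1.9)
})

test_that("effort allocation is proportional to profitability", {
  B <- matrix(1, 4, 2)
  expect_equal(allocate_effort(B, c(1, 0)), rep(1, 4))
  # all value in one cell
  B2 <- matrix(0, 4, 2); B2[3, 1] <- 5
  expect_equal(allocate_effort(B2, c(1, 0)), c(0, 0, 4, 0))
  # profitability 3:1 splits effort 0.75/0.25
  B3 <- matrix(c(3, 1), 2, 1)
  expect_equal(allocate_effort(B3, 1, total = 1), c(0.75, 0.25))
  # nothing profitable: uniform fallback
  expect_equal(allocate_effort(B2, c(1, 0), cost = 10), rep(1, 4))
})

test_that("a uniform unforced grid stays spatially uniform at baseline", {
  m <- test_model()
  g <- grid5()
  run <- run_simulation(m, g, n_months = 24, spinup_months = 0)
  for (i in seq_len(m$n)) {
    expect_lt(max(abs(run$B[24, , i] - m$B0[i])) / m$B0[i], 1e-9)
  }
})

test_that("spin-up relaxes a forced field back near baseline totals", {
  m <- test_model()
  g <- grid5()
  d <- gen_drivers(g, 12, seed = 2)
  er <- default_env_responses(test_web())
  run <- run_simulation(m, g, drivers = d, n_months = 12,
                        spinup_months = 24, env_responses = er)
  tot1 <- apply(run$B[1, , ], 2, sum)
  expect_true(all(abs(tot1 / (m$B0 * n_water(g)) - 1) < 0.35))
})

test_that("domain-wide severe forcing trips the stability screen", {
  w <- small_web()
  m <- calibrate_model(w)
  g <- grid5()
  b <- gen_blooms(g, 2, severe_years = 1, seed = 4)
  sc <- build_scenario_grid(target_group = "grouper")
  harsh <- sc[sc$target == "all_consumers" & sc$sensitivity == 1 &
                sc$slope_level == 4 & is.na(sc$foraging_curve), ][1, ]
  expect_error(
    run_simulation(m, g, blooms = b, scenario = harsh, n_months = 24,
                   spinup_months = 6),
    class = "rt_instability"
  )
})

test_that("the recorded loss tensor is the per-cell kill A * B", {
  m <- calibrate_model(toy_web())
  g <- grid5()
  S <- n_water(g)
  b <- zero_blooms(g, 12)
  b$x[5, ] <- 1e5                       # one month at the inflection
  sc <- build_scenario_grid(target_group = "grazer")
  scen <- sc[sc$target == "all_consumers" & is.na(sc$foraging_curve), ][1, ]
  scen$c <- 1e5; scen$b <- 2            # pin the curve: A(1e5) = 0.5
  run <- run_simulation(m, g, blooms = b, scenario = scen, n_months = 12,
                        spinup_months = 0)
  # loss in the bloom month is half the standing grazer biomass
  expect_equal(run$loss[5, , 2], rep(0.5 * m$B0[2], S), tolerance = 1e-9)
  expect_true(all(run$loss[-5, , ] == 0))
  # no producer or detritus losses
  expect_true(all(run$loss[, , c(1, 3)] == 0))
})
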