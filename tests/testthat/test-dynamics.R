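test_that("foraging-arena consumption has its limiting behaviours", {
  expect_equal(consumption(0, 5, a = 1, v = 2), 0)
  # v -> infinity: mass action a * Bprey * Bpred / 2
  expect_equal(consumption(3, 5, a = 1, v = 1e12),
               1 * 3 * 5 / 2, tolerance = 1e-9)
  # arena supply bound Q <= v * B_prey, over random argument draws
  withr::with_seed(1, {
    for (k in 1:50) {
      bp <- runif(1, 0, 100); bq <- runif(1, 0, 100)
      a <- runif(1, 0, 10); v <- runif(1, 0.1, 50)
      expect_lte(consumption(bp, bq, a, v), v * bp + 1e-12)
    }
  })
  # capacity shrinks the flow
  expect_lt(consumption(3, 5, 1, 2, capacity = 0.5),
            consumption(3, 5, 1, 2, capacity = 1))
})

test_that("calibrated rates reproduce the baseline flows exactly", {
  m <- test_model()
  for (j in which(m$is_cons)) {
    for (i in which(m$Q0[j, ] > 0)) {
      q <- consumption(m$B0[i], m$B0[j], m$a[j, i], m$v_rate[j, i])
      expect_equal(q, m$Q0[j, i], tolerance = 1e-12)
    }
  }
})

test_that("the mass-balance state is a fixed point of the dynamics", {
  m <- test_model()
  run <- run_cell(m, 120)
  drift <- abs(run$B[120, ] - m$B0) / m$B0
  expect_lt(max(drift), 1e-6)   # < 1e-6 relative per year, held 10 years
})

test_that("doubling fishing pressure depresses the stock", {
  m <- test_model()
  i <- which(m$groups$group == "grouper")
  eff2 <- setNames(rep(1, length(m$fleet_names)), m$fleet_names)
  # double every fleet's effort: grouper F doubles
  st <- list(B = m$B0, effort = 2 * eff2)
  for (t in 1:12) st <- step_cell(st, m)
  expect_lt(st$B[i], m$B0[i])
  # and the trajectory is monotone down over the first months
  st <- list(B = m$B0, effort = 2 * eff2)
  prev <- m$B0[i]
  for (t in 1:6) {
    st <- step_cell(st, m)
    expect_lt(st$B[i], prev)
    prev <- st$B[i]
  }
})

test_that("extra other-mortality multipliers act additively", {
  m <- calibrate_model(toy_web())
  i <- 2                                  # the unfished grazer
  st0 <- step_cell(list(B = m$B0), m)
  st1 <- step_cell(list(B = m$B0, m0mult = c(0, 1, 0)), m)
  expect_equal(unname(st0$B[i]), m$B0[i], tolerance = 1e-12)
  expect_lt(st1$B[i], st0$B[i])
  # mult = 0 recovers baseline exactly
  st2 <- step_cell(list(B = m$B0, m0mult = rep(0, 3)), m)
  expect_equal(st2$B, st0$B)
})

test_that("a group with no losses cannot shrink", {
  m <- calibrate_model(toy_web())
  # grazer: no predators, no catch; suppress its other mortality
  m$m0base[2] <- 0
  st <- list(B = m$B0)
  prev <- m$B0[2]
  for (t in 1:12) {
    st <- step_cell(st, m)
    expect_gte(st$B[2], prev - 1e-12)
    prev <- st$B[2]
  }
})

test_that("the per-group budget closes at every sub-step", {
  m <- test_model()
  withr::with_seed(4, B <- matrix(m$B0 * runif(m$n, 0.5, 2), 1, m$n))
  cap <- matrix(1, 1, m$n)
  F_mat <- matrix(m$F0, 1, m$n)
  dt <- 1 / 48
  out <- dyn_substep(B, m, cap, 1, 1, F_mat, matrix(0, 1, m$n), dt)
  det <- m$det[1]
  live <- setdiff(seq_len(m$n), det)
  lhs <- out$B[1, live] - B[1, live]
  rhs <- dt * (out$gains[1, live] -
                 (out$pred[1, live] + out$fish[1, live] + out$m0[1, live]))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("producer growth follows the clipped chlorophyll anomaly", {
  expect_equal(producer_growth(10, 2, 1, pb = 100, baseline = 2), 1000)
  expect_equal(producer_growth(10, 0, 1, pb = 100, baseline = 2),
               0.1 * 1000)
  expect_lte(producer_growth(10, 4, 1, pb = 100, baseline = 2), 2 * 1000)
  expect_equal(producer_growth(10, 1e6, 1, pb = 100, baseline = 2),
               10 * 1000)  # ceiling at 10x
  # capacity scales production linearly
  expect_equal(producer_growth(10, 2, 0.25, pb = 100, baseline = 2), 250)
})

test_that("non-finite states raise the instability signal", {
  m <- calibrate_model(toy_web())
  expect_error(step_cell(list(B = c(NaN, 1, 1)), m),
               class = "rt_instability")
})
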