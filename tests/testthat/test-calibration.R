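test_that("percent bias matches its closed form", {
  ref <- c(2, 4, 6, 8)
  expect_equal(pbias(ref, ref), 0)
  expect_equal(pbias(1.1 * ref, ref), 10)
  expect_equal(pbias(rep(0, 4), ref), -100)
  expect_error(pbias(ref, rep(0, 4)), "all-zero")
  # total score sums absolute per-group biases
  sim <- cbind(1.1 * ref, 0.8 * ref)
  expect_equal(total_pbias(sim, cbind(ref, ref)), 10 + 20)
})

test_that("the lognormal log-likelihood peaks at the reference", {
  ref <- c(1, 2, 3, 5, 8)
  sigma <- 0.3
  # zero residuals: T * log(1 / (sigma sqrt(2 pi)))
  expect_equal(loglik(ref, ref, sigma),
               length(ref) * log(1 / (sigma * sqrt(2 * pi))))
  # scaling the simulation by e^sigma costs T/2
  expect_equal(loglik(ref, ref, sigma) - loglik(exp(sigma) * ref, ref, sigma),
               length(ref) / 2)
  # invariant under a consistent reordering of time
  o <- c(3, 1, 5, 2, 4)
  expect_equal(loglik(ref[o], ref[o] * 1.1, sigma),
               loglik(ref, ref * 1.1, sigma))
  expect_error(loglik(c(-1, 1), c(1, 1)), "positive")
})

test_that("candidate grids span the documented ranges", {
  gv <- candidate_grid("v")
  gd <- candidate_grid("D")
  expect_length(gv, 20)
  expect_length(gd, 20)
  expect_equal(range(gv), c(1.01, 1e4))
  expect_equal(range(gd), c(0.1, 10))
  expect_error(candidate_grid("x"), "unknown")
})

cheap_runner <- function() {
  # analytic stand-in for the simulator: monthly series whose level is set
  # by each parameter's log offset from its reference value
  ref_par <- c("v:a" = 2, "v:b" = 8, "D:a" = 1)
  function(params) {
    t <- 1:24
    sapply(seq_along(ref_par), function(k) {
      (1 + 0.1 * k) * exp(0.3 * (log(params[k]) - log(ref_par[k]))) +
        0 * t + 0.01 * sin(t)
    })
  }
}

test_that("one-at-a-time sensitivity ranks the live parameters first", {
  runner <- cheap_runner()
  params <- c("v:a" = 2, "v:b" = 8, "D:a" = 1, "D:dead" = 1)
  # D:dead has no pathway into the series
  runner2 <- function(p) runner(p[1:3])
  ref <- runner2(params)
  sens <- oat_sensitivity(runner2, params, ref)
  expect_equal(sens$parameter[4], "D:dead")
  expect_equal(sens$sensitivity[4], 0)
  # parameters entering through the same symmetric pathway score identically
  runner3 <- function(p) {
    out <- runner(p[1:3])
    out[, 3] <- 2 * (p[["D:a"]] * p[["D:dead"]])^0.3 + 0.01 * sin(1:24)
    out
  }
  ref3 <- runner3(params)
  s3 <- oat_sensitivity(runner3, params, ref3)
  expect_equal(s3$sensitivity[s3$parameter == "D:a"],
               s3$sensitivity[s3$parameter == "D:dead"], tolerance = 1e-9)
})

test_that("the iterative fit respects its stopping contracts", {
  runner <- cheap_runner()
  params <- c("v:a" = 2, "v:b" = 8, "D:a" = 1)
  ref <- runner(params)
  # max_iter = 0: incumbents returned untouched
  fit0 <- iterate_fit(runner, params, ref, max_iter = 0)
  expect_equal(fit0$params, params)
  expect_equal(fit0$iterations, 0L)
  # already optimal (score 0): one pass, nothing accepted
  fit1 <- iterate_fit(runner, params, ref, max_iter = 5)
  expect_equal(fit1$iterations, 1L)
  expect_equal(sum(fit1$records$accepted), 0)
  expect_equal(fit1$params, params)
})

test_that("the fit recovers a shifted parameter and never degrades", {
  runner <- cheap_runner()
  params <- c("v:a" = 2, "v:b" = 8, "D:a" = 1)
  truth <- params
  truth["v:b"] <- candidate_grid("v")[13]
  ref <- runner(truth)
  fit <- iterate_fit(runner, params, ref, max_iter = 5)
  expect_equal(unname(fit$params["v:b"]), candidate_grid("v")[13])
  expect_lt(fit$score, 0.01 * fit$initial_score)
  # accepted-score trajectory is non-increasing
  acc <- fit$records[fit$records$accepted, ]
  expect_true(all(diff(acc$pbias_total) <= 1e-9))
})
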