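test_that("generated food webs are balanced and fully tagged", {
  web <- test_web()
  rep <- check_balance(web)
  expect_lt(max(abs(rep$residual)), 1e-9)
  g <- web$groups
  living <- g$type != "detritus"
  expect_true(all(g$ee[living] >= 0 & g$ee[living] <= 1))
  expect_true(all(g$trait %in% c("upper TL pelagic", "lower TL pelagic",
                                 "demersal", "reef-associated",
                                 "benthic invertebrate", "producer",
                                 "detritus")))
  expect_true(all(nzchar(g$taxon)))
  cons <- g$type == "consumer"
  expect_equal(unname(rowSums(web$diet[cons, , drop = FALSE])),
               rep(1, sum(cons)))
  # every fleet lands something
  fl <- dplyr::summarise(dplyr::group_by(web$fleets, fleet),
                         y = sum(catch))
  expect_true(all(fl$y > 0))
  expect_equal(sum(g$focal), 1)
  # 300-30-3 dispersal rule follows the trait tags
  expect_equal(g$dispersal, dispersal_300_30_3(g$trait))
})

test_that("food-web generation is a pure function of its arguments", {
  expect_identical(gen_foodweb(12, 2, seed = 7), gen_foodweb(12, 2, seed = 7))
  expect_false(identical(gen_foodweb(12, 2, seed = 7)$groups$biomass,
                         gen_foodweb(12, 2, seed = 8)$groups$biomass))
  expect_error(gen_foodweb(3, 1, seed = 1))
})

test_that("generated webs balance across sizes and seeds", {
  for (n in c(4, 8, 12)) {
    for (seed in 1:3) {
      web <- gen_foodweb(n, 1 + seed %% 2, seed = seed)
      expect_lt(max(abs(check_balance(web)$residual)), 1e-9)
    }
  }
})

test_that("driver stacks have the advertised structure", {
  g <- grid5()
  d <- gen_drivers(g, 24, seed = 2)
  expect_identical(d, gen_drivers(g, 24, seed = 2))
  # static fields repeat every month
  expect_equal(d$vars$depth[1, ], d$vars$depth[13, ])
  # seasonal period 12: month 1 and 13 differ only by the noise term
  d0 <- gen_drivers(g, 24, seed = 2, noise_sd = 0)
  expect_equal(d0$vars$sst[1, ], d0$vars$sst[13, ])
  expect_equal(d0$vars$sss[5, ], d0$vars$sss[17, ])
  # depth grows away from the coast
  wc_coast <- gen_drivers(g, 12, seed = 3)
  rho <- cor(wc_coast$vars$depth[1, ],
             g$coast_distance[!g$land][order(row(g$land)[!g$land],
                                             col(g$land)[!g$land])],
             method = "spearman")
  expect_gt(rho, 0)
  expect_false(anyNA(unlist(d$vars)))
})

test_that("bloom stacks are coastal, seasonal and severity-ordered", {
  g <- fixture("grid8", function() make_grid(8, 8, 10, "west"))
  b <- gen_blooms(g, n_years = 3, severe_years = 2, seed = 3)
  expect_identical(b, gen_blooms(g, n_years = 3, severe_years = 2, seed = 3))
  expect_true(all(b$x >= 0))
  # land cells are zero in the raster view
  r <- as_raster(b$x[9, ], g, fill = 0)
  expect_true(all(r[g$land] == 0))
  # outside the bloom season every cell sits at background
  jan <- b$x[c(1, 13, 25), ]
  expect_true(all(jan == b$background))
  # severe year has the largest footprint
  fp <- bloom_footprint(b, threshold = 1e5)
  expect_equal(fp$year[which.max(fp$footprint_cells)], 2)
  expect_true(all(fp$footprint_cells[2] > fp$footprint_cells[-2]))
  # coastal mean >= offshore mean in active months
  wc <- g$coast_distance[!g$land]
  ord <- order(row(g$land)[!g$land], col(g$land)[!g$land])
  coast_km <- wc[ord]
  coastal <- coast_km <= stats::quantile(coast_km, 0.3)
  active <- which(apply(b$x, 1, max) > b$background)
  for (t in active) {
    expect_gte(mean(b$x[t, coastal]), mean(b$x[t, !coastal]))
  }
})

test_that("a bloom-free schedule stays below the quiet-year ceiling", {
  g <- grid5()
  b <- gen_blooms(g, n_years = 2, severe_years = integer(), seed = 9,
                  peak_range = c(4, 5.3), n_kernels = 2)
  ceiling_quiet <- b$background + 2 * 10^5.3
  expect_lt(max(b$x), ceiling_quiet)
})

test_that("surveys are unbiased, seeded samples of the trajectory", {
  model <- calibrate_model(toy_web())
  g <- grid5()
  run <- run_simulation(model, g, n_months = 12, spinup_months = 0)
  des <- list(timesteps = c(3, 9), groups = "grazer", n_stations = 10,
              sigma = 0)
  sv <- gen_surveys(run, des, seed = 1)
  expect_identical(sv, gen_surveys(run, des, seed = 1))
  # zero observation error reproduces cell biomass exactly
  expect_equal(sv$observed,
               run$B[cbind(sv$timestep, sv$cell,
                           match(sv$group, run$groups$group))])
  # mean-corrected lognormal error: sample mean within 3 SE of truth
  des2 <- list(timesteps = 6, groups = "grazer", n_stations = 500,
               sigma = 0.3)
  sv2 <- gen_surveys(run, des2, seed = 2)
  b_true <- mean(run$B[6, sv2$cell, 2])
  se <- sd(sv2$observed) / sqrt(nrow(sv2))
  expect_lt(abs(mean(sv2$observed) - b_true), 3 * se)
  # designs must reference cells on the water grid
  expect_error(gen_surveys(run, list(timesteps = 1, groups = "grazer",
                                     cells = 10 + n_water(g)), seed = 1),
               "outside the grid")
  expect_error(gen_surveys(run, list(timesteps = 1, groups = "nope"),
                           seed = 1), "unknown groups")
})
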