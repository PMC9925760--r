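# Shared fixtures, built in code and memoised per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

# hand-balanced 3-group web: producer -> grazer, plus detritus.
# Producer EE = (1 * 50 * 1) / (10 * 100) = 0.05 by hand.
toy_groups <- function() {
  tibble::tibble(
    group = c("phyto", "grazer", "detritus"),
    type = c("producer", "consumer", "detritus"),
    biomass = c(10, 1, 5),
    pb = c(100, 5, 0),
    qb = c(0, 50, 0),
    ee = NA_real_,
    catch = 0,
    trait = c("producer", "lower TL pelagic", "detritus"),
    taxon = c("phytoplankton", "fishes", "detritus"),
    harvested = FALSE, juvenile = FALSE, focal = c(FALSE, TRUE, FALSE),
    dispersal = c(3, 300, 3)
  )
}

toy_diet <- function() {
  g <- toy_groups()$group
  d <- matrix(0, 3, 3, dimnames = list(g, g))
  d["grazer", "phyto"] <- 1
  d
}

toy_web <- function() {
  gr <- toy_groups()
  gr$ee[gr$type == "detritus"] <- 0
  solve_balance(gr, toy_diet())
}

# a slow-rate web (annual rates << 1) where one month of dynamics barely
# moves biomass; used for "immediately after" contrasts
slow_web <- function() {
  gr <- toy_groups()
  gr$pb <- c(0.4, 0.05, 0)
  gr$qb <- c(0, 0.25, 0)
  gr$ee[gr$type == "detritus"] <- 0
  solve_balance(gr, toy_diet())
}

test_web <- function() fixture("web10", function() gen_foodweb(10, 2, seed = 1))
test_model <- function() fixture("model10", function() calibrate_model(test_web()))
small_web <- function() fixture("web6", function() gen_foodweb(6, 1, seed = 5))

# 2x2 grid with a single water cell (for spatial/single-cell equivalence)
one_cell_grid <- function() {
  mask <- matrix(TRUE, 2, 2)
  mask[2, 2] <- FALSE
  make_grid(2, 2, cell_km = 10, land = mask)
}

grid5 <- function() fixture("grid5", function() make_grid(5, 5, 10, "west"))
grid15 <- function() fixture("grid15", function() make_grid(15, 15, 10, "west"))
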