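#' Generate monthly environmental driver rasters
#'
#' Emulates the environmental inputs of a shelf ecosystem model on the
#' package grid: static depth (increasing away from the coast) and seabed
#' rugosity, and monthly sea surface temperature (SST), sea bottom
#' temperature (SBT), sea surface salinity (SSS) and chlorophyll. Dynamic
#' variables follow a sinusoidal seasonal cycle (period 12 months) plus a
#' smooth north-south/cross-shelf spatial gradient plus seeded smooth
#' noise. Land cells are `NA`.
#'
#' @param grid An [make_grid()] grid.
#' @param n_months Number of months (>= 12).
#' @param seed Integer seed; the stack is a pure function of its arguments.
#' @param noise_sd Standard deviation of the monthly noise fields (in each
#'   variable's units).
#' @return An `rt_drivers` object: list with `vars` (named list of
#'   `n_months x n_water` matrices; static variables repeated each month),
#'   `baseline` (named reference value per variable, the value at which
#'   environmental suitability is 1), `grid`, `n_months`.
#' @examples
#' g <- make_grid(6, 6)
#' d <- gen_drivers(g, 24, seed = 2)
#' names(d$vars)
#' @export
gen_drivers <- function(grid, n_months, seed = 1, noise_sd = 0.3) {
  stopifnot(inherits(grid, "rt_grid"), n_months >= 12)
  withr::local_seed(seed)

  wc <- water_coords(grid)
  S <- nrow(wc)
  month_of <- ((seq_len(n_months) - 1) %% 12) + 1

  # static fields
  depth <- 5 + 1.8 * wc$coast_km + 3 * smooth_field(grid, wc)
  depth <- pmax(depth, 1)
  rugosity <- pmax(0.01, 0.5 + 0.3 * smooth_field(grid, wc))

  season <- function(amp, peak_month) {
    amp * cos(2 * pi * (month_of - peak_month) / 12)
  }
  grad_ns <- (wc$row - mean(wc$row)) / max(1, diff(range(wc$row)))
  grad_cs <- (wc$coast_km - mean(wc$coast_km)) /
    max(1, diff(range(wc$coast_km)))

  dyn <- function(base, amp, peak, grad, sdn) {
    m <- outer(season(amp, peak), rep(1, S)) +
      outer(rep(1, n_months), base + grad) +
      matrix(rnorm(n_months * S, 0, sdn), n_months, S)
    m
  }
  sst <- dyn(25, 4, 8, -2 * grad_ns, noise_sd)
  sbt <- dyn(22, 2.5, 9, -1.5 * grad_ns - 2 * grad_cs, noise_sd)
  sss <- dyn(35, 0.8, 5, 1.5 * grad_cs, noise_sd * 0.5)
  # log-scale chlorophyll: modest seasonal cycle (+/- 15%) and coastal
  # enrichment, so forced primary production stays within the range a
  # persistent shelf ecosystem can absorb
  chl_ref <- 2
  chl <- chl_ref * exp(0.15 * outer(season(1, 9), rep(1, S)) -
                         0.25 * outer(rep(1, n_months), grad_cs) +
                         matrix(rnorm(n_months * S, 0, noise_sd * 0.1),
                                n_months, S))

  static_stack <- function(v) matrix(rep(v, each = n_months), n_months, S)
  structure(
    list(
      vars = list(
        depth = static_stack(depth), rugosity = static_stack(rugosity),
        sst = sst, sbt = sbt, sss = sss, chlorophyll = chl
      ),
      baseline = c(depth = mean(depth), rugosity = mean(rugosity),
                   sst = 25, sbt = 22, sss = 35, chlorophyll = chl_ref),
      grid = grid, n_months = as.integer(n_months)
    ),
    class = "rt_drivers"
  )
}

# smooth zero-mean random field over water cells (iterated 4-neighbour
# averaging of white noise)
smooth_field <- function(grid, wc = water_coords(grid), n_iter = 4) {
  nb <- water_neighbours(grid)
  z <- rnorm(nrow(wc))
  for (k in seq_len(n_iter)) {
    acc <- z; cnt <- rep(1, length(z))
    for (d in nb) {
      ok <- !is.na(d)
      acc[ok] <- acc[ok] + z[d[ok]]
      cnt[ok] <- cnt[ok] + 1
    }
    z <- acc / cnt
  }
  as.numeric(scale(z))
}

#' Constant (baseline) driver stack
#'
#' Every variable is held at its reference value in every cell and month —
#' the neutral environment under which habitat capacity is exactly 1.
#' Useful for fixed-point checks and as the spin-up environment.
#'
#' @inheritParams gen_drivers
#' @return An `rt_drivers` object.
#' @export
constant_drivers <- function(grid, n_months) {
  d <- gen_drivers(grid, max(12, n_months), seed = 0, noise_sd = 0)
  for (v in names(d$vars)) {
    d$vars[[v]][] <- d$baseline[[v]]
  }
  d$n_months <- as.integer(n_months)
  d$vars <- lapply(d$vars, function(m) m[rep_len(seq_len(nrow(m)), n_months), , drop = FALSE])
  d
}

#' Assign environmental response functions to groups
#'
#' Mirrors the convention of linking bottom temperature to demersal,
#' reef-associated and benthic groups and surface temperature to pelagic
#' groups. Each response is a logistic preference in the driver variable,
#' evaluated *relative to its value at the driver's baseline* and capped at
#' 1, so that baseline conditions give suitability 1.
#'
#' @param web An `rt_foodweb`.
#' @param width Logistic width (driver units) controlling how fast
#'   suitability decays away from the preferred range.
#' @return An `rt_env_responses`: named list (one per group) of lists with
#'   `var`, `mid`, `scale`, `direction`; producers and detritus get none.
#' @export
default_env_responses <- function(web, width = 3) {
  g <- web$groups
  resp <- setNames(vector("list", nrow(g)), g$group)
  for (i in seq_len(nrow(g))) {
    if (g$type[i] != "consumer") { resp[[i]] <- list(); next }
    if (g$trait[i] %in% c("demersal", "reef-associated", "benthic invertebrate")) {
      resp[[i]] <- list(list(var = "sbt", mid = 16, scale = width, direction = 1))
    } else {
      resp[[i]] <- list(list(var = "sst", mid = 18, scale = width, direction = 1))
    }
  }
  structure(resp, class = "rt_env_responses")
}

# evaluate one logistic environmental response (unnormalized)
env_response_value <- function(x, r) {
  plogis(r$direction * (x - r$mid) / r$scale)
}

#' Habitat capacity of a cell for a group
#'
#' The product of the group's environmental responses (each normalized to
#' its value at the driver baseline and capped at 1) times the sublethal
#' foraging multiplier, floored at `eps` so capacity stays positive.
#'
#' @param drivers Named numeric vector (or list) of driver values for the
#'   cell.
#' @param responses The group's entry of [default_env_responses()] (a list
#'   of response descriptors; may be empty).
#' @param baseline Named baseline driver values (suitability 1 there).
#' @param foraging Sublethal foraging multiplier in (0, 1\] (default 1).
#' @param eps Capacity floor (default `1e-4`).
#' @return Capacity in \[`eps`, 1\].
#' @examples
#' habitat_capacity(c(sst = 25), list(), c(sst = 25))  # 1
#' @export
habitat_capacity <- function(drivers, responses, baseline,
                             foraging = 1, eps = 1e-4) {
  cap <- 1
  for (r in responses) {
    v0 <- env_response_value(baseline[[r$var]], r)
    cap <- cap * pmin(1, env_response_value(drivers[[r$var]], r) / v0)
  }
  pmax(eps, cap * foraging)
}

# vectorized capacity over all water cells for one group and month
capacity_field <- function(drivers, month, responses, foraging, eps = 1e-4) {
  S <- ncol(drivers$vars[[1]])
  cap <- rep(1, S)
  for (r in responses) {
    v0 <- env_response_value(drivers$baseline[[r$var]], r)
    cap <- cap * pmin(1, env_response_value(drivers$vars[[r$var]][month, ], r) / v0)
  }
  pmax(eps, cap * foraging)
}
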