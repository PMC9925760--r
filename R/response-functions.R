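#' Lethal and sublethal logistic responses to bloom concentration
#'
#' The lethal response gives the proportion of a group's biomass killed in a
#' cell over one monthly timestep as a logistic function of *Karenia brevis*
#' concentration \eqn{x} (cells L^-1):
#' \deqn{A(x) = \frac{1}{1 + (x/c)^{-b}},}
#' with inflection \eqn{c} (where half the biomass is killed) and slope
#' \eqn{b > 0}. \eqn{A(0) = 0} by continuity.
#'
#' The sublethal (foraging) response is a decreasing logistic multiplier on
#' habitat capacity, representing reduced feeding and avoidance at
#' concentrations below lethal levels:
#' \deqn{f(x) = \frac{1}{1 + e^{k (x - c_f)}},}
#' with inflection \eqn{c_f} (a 25/50/75% fraction of the paired mortality
#' inflection) and constant rate \eqn{k = 5\times10^{-5}} L cells^-1, so
#' changing the inflection translates the curve along the x-axis without
#' changing its shape.
#'
#' @param c Inflection concentration, cells L^-1 (> 0).
#' @param b Slope of the lethal curve (> 0).
#' @name response_functions
NULL

#' @rdname response_functions
#' @return `mortality_response()` and `foraging_response()` return
#'   parameter objects of class `rt_mortality_response` /
#'   `rt_foraging_response`.
#' @export
mortality_response <- function(c, b) {
  stopifnot(c > 0, b > 0)
  structure(list(c = c, b = b), class = "rt_mortality_response")
}

#' @rdname response_functions
#' @param inflection Inflection concentration of the foraging curve,
#'   cells L^-1.
#' @param rate Linear-x logistic rate, L cells^-1 (default `5e-5`).
#' @export
foraging_response <- function(inflection, rate = 5e-5) {
  stopifnot(inflection > 0, rate > 0)
  structure(list(inflection = inflection, rate = rate),
            class = "rt_foraging_response")
}

#' Proportion of biomass killed at a bloom concentration
#'
#' @param x Concentration, cells L^-1 (vectorised, >= 0).
#' @param r An `rt_mortality_response`.
#' @return `A` in \[0, 1): the monthly kill proportion, clipped to
#'   `1 - 1e-12` so it can always be annualized.
#' @examples
#' r <- mortality_response(c = 1e5, b = 2)
#' mortality_proportion(1e5, r)  # 0.5 at the inflection
#' @export
mortality_proportion <- function(x, r) {
  stopifnot(all(x >= 0))
  a <- ifelse(x == 0, 0, 1 / (1 + (x / r$c)^(-r$b)))
  pmin(a, 1 - 1e-12)
}

#' Sublethal foraging multiplier at a bloom concentration
#'
#' @param x Concentration, cells L^-1 (vectorised, >= 0).
#' @param r An `rt_foraging_response`.
#' @return Multiplier in (0, 1\], decreasing in `x`, equal to 0.5 at the
#'   inflection.
#' @export
foraging_multiplier <- function(x, r) {
  stopifnot(all(x >= 0))
  1 / (1 + exp(pmin(700, r$rate * (x - r$inflection))))
}

# sublethal capacity multiplier as used by the simulator: the foraging
# curve relative to its no-bloom value, so zero concentration is exactly
# neutral (1) and the multiplier decays toward 0 as the bloom intensifies
foraging_capacity <- function(x, r) {
  foraging_multiplier(x, r) / foraging_multiplier(0, r)
}

#' Convert a monthly kill proportion to an annual instantaneous rate
#'
#' \deqn{\hat A = -\ln(1 - A) \cdot 12,} so that a constant rate
#' \eqn{\hat A} applied over one month removes exactly the proportion `A`:
#' `exp(-annualize(A) / 12) == 1 - A`.
#'
#' @param A Monthly kill proportion in \[0, 1).
#' @return Annual instantaneous mortality, yr^-1.
#' @export
annualize <- function(A) {
  stopifnot(all(A >= 0))
  if (any(A >= 1)) abort("A must be < 1 (clip before annualizing)")
  -log1p(-A) * 12
}

#' Scale an annualized red-tide rate to the baseline other mortality
#'
#' Returns the multiplier `M0mult = A_hat / m0base`. The simulator treats
#' the multiplier as *additional* mortality, i.e. effective other mortality
#' is `m0base * (1 + M0mult)`, so `M0mult = 0` recovers the baseline and
#' `M0mult = 1` doubles it. When `m0base` is 0 (a group with ecotrophic
#' efficiency 1) the annualized rate cannot be expressed as a multiplier;
#' the rate itself is returned in the `absolute` field and flagged.
#'
#' @param a_hat Annual instantaneous red-tide mortality, yr^-1.
#' @param m0base Baseline other mortality, yr^-1 (>= 0).
#' @return A list with `mult` (NA when `m0base` is 0), `absolute` (the rate
#'   `a_hat`), and `direct` (`TRUE` when the rate must be applied as an
#'   absolute addition because `m0base` is 0).
#' @export
m0_multiplier <- function(a_hat, m0base) {
  stopifnot(a_hat >= 0, m0base >= 0)
  if (m0base == 0) {
    list(mult = NA_real_, absolute = a_hat, direct = TRUE)
  } else {
    list(mult = a_hat / m0base, absolute = a_hat, direct = FALSE)
  }
}

#' Build the library of lethal response curves
#'
#' The default library crosses 5 inflection concentrations (log-spaced over
#' 10^4.5 to 10^6.5 cells L^-1, spanning the range over which *K. brevis*
#' blooms harm marine fauna) with 4 slope scalars, giving 20 curves of
#' graded sensitivity. Ordering is inflection-major, slope-minor.
#'
#' @param inflections Numeric vector of inflection concentrations
#'   (cells L^-1).
#' @param slopes Numeric vector of logistic slopes.
#' @return A tibble of class `rt_mortality_library` with columns
#'   `curve` (id `"M<ii>"`), `c`, `b`, `sensitivity` (rank of the
#'   inflection, 1 = most sensitive), `slope_level`.
#' @export
build_mortality_library <- function(inflections = 10^seq(4.5, 6.5, length.out = 5),
                                    slopes = c(1, 2, 4, 8)) {
  stopifnot(all(inflections > 0), all(slopes > 0))
  tab <- tidyr::expand_grid(
    sensitivity = seq_along(inflections),
    slope_level = seq_along(slopes)
  )
  tab$c <- inflections[tab$sensitivity]
  tab$b <- slopes[tab$slope_level]
  tab$curve <- sprintf("M%02d", seq_len(nrow(tab)))
  out <- tab[, c("curve", "c", "b", "sensitivity", "slope_level")]
  class(out) <- c("rt_mortality_library", class(out))
  out
}

#' Build the library of sublethal (foraging) response curves
#'
#' For each distinct mortality inflection, three foraging curves are placed
#' at 25, 50 and 75% of that inflection (sublethal effects are felt below
#' lethal concentrations), all sharing the constant rate `5e-5` L cells^-1
#' so the curves are x-translations of one shape. Five inflection levels
#' times three fractions gives 15 curves.
#'
#' @param mortality An `rt_mortality_library`.
#' @param fractions Fractions of the mortality inflection (default
#'   `c(0.25, 0.5, 0.75)`).
#' @param rate Shared logistic rate, L cells^-1.
#' @return A tibble of class `rt_foraging_library` with columns `curve`
#'   (`"F<ii>"`), `sensitivity`, `fraction`, `inflection`, `rate`.
#' @export
build_foraging_library <- function(mortality = build_mortality_library(),
                                   fractions = c(0.25, 0.5, 0.75),
                                   rate = 5e-5) {
  lev <- dplyr::distinct(as_tibble(mortality)[, c("sensitivity", "c")])
  tab <- tidyr::expand_grid(sensitivity = lev$sensitivity, fraction = fractions)
  tab <- dplyr::left_join(tab, lev, by = "sensitivity")
  tab$inflection <- tab$fraction * tab$c
  tab$rate <- rate
  tab$curve <- sprintf("F%02d", seq_len(nrow(tab)))
  out <- tab[, c("curve", "sensitivity", "fraction", "inflection", "rate")]
  class(out) <- c("rt_foraging_library", class(out))
  out
}

#' Build the full combinatorial scenario grid
#'
#' Crosses the response-function libraries into the simulation ensemble:
#' 20 mortality-only configurations plus 60 combining each mortality curve
#' with its three paired foraging curves (same inflection level) make 80
#' configurations, each run once with forcing applied to every consumer
#' group and once with forcing applied to a single named group — 160
#' scenarios in total.
#'
#' @param mortality An `rt_mortality_library`.
#' @param foraging An `rt_foraging_library` built from it.
#' @param target_group Name of the single group for the single-target half
#'   of the ensemble.
#' @return A tibble of class `rt_scenarios`, one row per scenario:
#'   `scenario` (id), `mortality_curve`, `c`, `b`, `foraging_curve`
#'   (NA for mortality-only), `fraction`, `inflection`, `rate`,
#'   `target` (`"all_consumers"` or `"single"`), `target_group`.
#' @export
build_scenario_grid <- function(mortality = build_mortality_library(),
                                foraging = build_foraging_library(mortality),
                                target_group = "grouper") {
  m <- as_tibble(mortality)
  f <- as_tibble(foraging)
  only <- dplyr::mutate(m,
    foraging_curve = NA_character_, fraction = NA_real_,
    inflection = NA_real_, rate = NA_real_
  )
  both <- dplyr::inner_join(
    m, dplyr::rename(f, foraging_curve = "curve"),
    by = "sensitivity", relationship = "many-to-many"
  )
  cfg <- dplyr::bind_rows(only, both)
  cfg <- dplyr::rename(cfg, mortality_curve = "curve")
  cfg <- cfg[, c("mortality_curve", "c", "b", "sensitivity", "slope_level",
                 "foraging_curve", "fraction", "inflection", "rate")]
  out <- dplyr::bind_rows(
    dplyr::mutate(cfg, target = "all_consumers",
                  target_group = NA_character_),
    dplyr::mutate(cfg, target = "single", target_group = target_group)
  )
  out$scenario <- sprintf(
    "S%03d_%s%s_%s", seq_len(nrow(out)), out$mortality_curve,
    ifelse(is.na(out$foraging_curve), "", paste0("_", out$foraging_curve)),
    ifelse(out$target == "all_consumers", "all", "one")
  )
  out <- out[, c("scenario", "mortality_curve", "c", "b", "sensitivity",
                 "slope_level", "foraging_curve", "fraction", "inflection",
                 "rate", "target", "target_group")]
  class(out) <- c("rt_scenarios", class(out))
  out
}

# one scenario row -> evaluation pieces used by the engine
scenario_functions <- function(scen) {
  stopifnot(nrow(scen) == 1)
  mr <- mortality_response(scen$c, scen$b)
  fr <- if (!is.na(scen$foraging_curve)) {
    foraging_response(scen$inflection, scen$rate)
  } else NULL
  list(mortality = mr, foraging = fr,
       target = scen$target, target_group = scen$target_group)
}

#' Evaluate red-tide forcing for one group in one cell
#'
#' Returns the pieces of forcing the simulator needs for a group exposed to
#' concentration `x`: the biomass killed (`loss = A * B`), the other
#' mortality multiplier (diagnostic; see [m0_multiplier()]), and the
#' sublethal foraging multiplier entering habitat capacity. Groups outside
#' the scenario's target set get the identity (`loss = 0`, `m0mult = 0`,
#' `foraging = 1`).
#'
#' @param B Biomass in the cell, t km^-2.
#' @param x Bloom concentration, cells L^-1.
#' @param scenario One row of an [build_scenario_grid()] table.
#' @param group Group name.
#' @param is_consumer Is the group a consumer (producers and detritus are
#'   never forced)?
#' @param m0base The group's baseline other mortality, yr^-1.
#' @return A list with `loss`, `m0mult`, `foraging`.
#' @export
apply_forcing <- function(B, x, scenario, group, is_consumer = TRUE,
                          m0base = NA_real_) {
  fns <- scenario_functions(scenario)
  targeted <- is_consumer &&
    (fns$target == "all_consumers" ||
       (fns$target == "single" && identical(group, fns$target_group)))
  if (!targeted) return(list(loss = 0 * B, m0mult = 0, foraging = 1))
  A <- mortality_proportion(x, fns$mortality)
  m0m <- if (!is.na(m0base) && m0base > 0) annualize(A) / m0base else NA_real_
  fv <- if (is.null(fns$foraging)) rep(1, length(x)) else foraging_capacity(x, fns$foraging)
  list(loss = A * B, m0mult = m0m, foraging = fv)
}

#' Plot a response-function library
#'
#' Draws every lethal curve (and, optionally, the paired foraging curves)
#' over a log concentration axis.
#'
#' @param mortality An `rt_mortality_library`.
#' @param foraging Optional `rt_foraging_library`.
#' @param xlim Concentration range, cells L^-1.
#' @return A ggplot object.
#' @export
plot_response_library <- function(mortality = build_mortality_library(),
                                  foraging = NULL,
                                  xlim = c(1e3, 1e8)) {
  x <- 10^seq(log10(xlim[1]), log10(xlim[2]), length.out = 300)
  mcurves <- purrr::pmap_dfr(
    as_tibble(mortality),
    function(curve, c, b, sensitivity, slope_level) {
      tibble(curve = curve, kind = "lethal (proportion killed)", x = x,
             value = mortality_proportion(x, mortality_response(c, b)),
             sensitivity = factor(sensitivity))
    }
  )
  dat <- mcurves
  if (!is.null(foraging)) {
    fcurves <- purrr::pmap_dfr(
      as_tibble(foraging),
      function(curve, sensitivity, fraction, inflection, rate) {
        tibble(curve = curve, kind = "sublethal (foraging multiplier)", x = x,
               value = foraging_multiplier(x, foraging_response(inflection, rate)),
               sensitivity = factor(sensitivity))
      }
    )
    dat <- dplyr::bind_rows(mcurves, fcurves)
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$value,
                                    group = .data$curve,
                                    colour = .data$sensitivity)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~kind, ncol = 1) +
    ggplot2::labs(x = expression(italic(K.~brevis)~concentration~(cells~L^-1)),
                  y = "response", colour = "sensitivity level") +
    ggplot2::theme_minimal()
}
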