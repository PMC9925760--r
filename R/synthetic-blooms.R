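#' Generate monthly synthetic bloom-concentration rasters
#'
#' Emulates *Karenia brevis* red-tide fields: spatially contiguous patches
#' built from Gaussian kernels anchored near the coast, active late summer
#' through autumn with the yearly peak in the configured peak months, and
#' amplitudes drawn on a log scale spanning roughly 10^3-10^7 cells L^-1.
#' In severe years both the peak concentration and the bloom footprint are
#' drawn from a higher range. Outside the bloom season (and in every month
#' of a "no-bloom" simulation) all water cells sit at the background
#' concentration; land cells are always 0.
#'
#' @param grid An [make_grid()] grid.
#' @param n_years Number of simulated years (12 months each).
#' @param severe_years Integer vector of severe-bloom years (subset of
#'   `1:n_years`).
#' @param seed Integer seed.
#' @param background Concentration where no bloom is present, cells L^-1
#'   (default `1e3`; the routinely detectable background).
#' @param season Months of the year with active blooms (default Jul-Nov).
#' @param peak_months Months at which the within-year envelope peaks
#'   (default Sep-Oct).
#' @param peak_range,severe_peak_range Log10 ranges of kernel peak
#'   amplitudes (cells L^-1) in ordinary and severe years.
#' @param n_kernels,severe_n_kernels Number of bloom patches per active
#'   month.
#' @return An `rt_blooms`: list with `x` (`n_months x n_water` matrix,
#'   cells L^-1), `severity` (per-year scalar: the year's 90th-percentile
#'   concentration), `events` (tibble log: year, month, centroid cell, peak
#'   concentration), `background`, `grid`, `n_months`.
#' @examples
#' g <- make_grid(8, 8)
#' b <- gen_blooms(g, n_years = 3, severe_years = 2, seed = 3)
#' @export
gen_blooms <- function(grid, n_years, severe_years = integer(), seed = 1,
                       background = 1e3,
                       season = 7:11, peak_months = 9:10,
                       peak_range = c(4, 5.3),
                       severe_peak_range = c(5.8, 7),
                       n_kernels = 2, severe_n_kernels = 5) {
  stopifnot(inherits(grid, "rt_grid"), n_years >= 1)
  if (!all(severe_years %in% seq_len(n_years))) {
    abort("severe_years must be a subset of the simulated years")
  }
  withr::local_seed(seed)

  wc <- water_coords(grid)
  S <- nrow(wc)
  n_months <- 12L * n_years
  x <- matrix(background, n_months, S)
  coastal <- which(wc$coast_km <= stats::quantile(wc$coast_km, 0.3))
  events <- list()

  for (yr in seq_len(n_years)) {
    severe <- yr %in% severe_years
    nk <- if (severe) severe_n_kernels else n_kernels
    pr <- if (severe) severe_peak_range else peak_range
    centres <- sample(coastal, nk, replace = TRUE)
    amps <- 10^runif(nk, pr[1], pr[2])
    sigmas <- runif(nk, 1, if (severe) 3 else 2)
    for (mo in season) {
      t <- (yr - 1) * 12 + mo
      # within-year envelope: 1 at the peak months, decaying into the
      # shoulders of the season
      env <- exp(-0.5 * (min(abs(mo - peak_months)) / 1.5)^2)
      for (k in seq_len(nk)) {
        d2 <- (wc$row - wc$row[centres[k]])^2 + (wc$col - wc$col[centres[k]])^2
        x[t, ] <- x[t, ] + env * amps[k] * exp(-d2 / (2 * sigmas[k]^2))
      }
      events[[length(events) + 1]] <- tibble(
        year = yr, month = mo, severe = severe,
        centroid_cell = centres, peak = env * amps
      )
    }
  }

  severity <- vapply(seq_len(n_years), function(yr) {
    rows <- ((yr - 1) * 12 + 1):(yr * 12)
    stats::quantile(x[rows, ], 0.9, names = FALSE)
  }, numeric(1))

  structure(
    list(x = x, severity = severity,
         events = if (length(events)) dplyr::bind_rows(events) else
           tibble(year = integer(), month = integer(), severe = logical(),
                  centroid_cell = integer(), peak = numeric()),
         background = background, grid = grid, n_months = n_months),
    class = "rt_blooms"
  )
}

#' Zero-concentration bloom stack
#'
#' All water cells at concentration 0 in every month — the no-red-tide
#' forcing under which every scenario must reproduce the baseline run.
#'
#' @inheritParams gen_blooms
#' @param n_months Number of months.
#' @return An `rt_blooms` with `x` identically 0.
#' @export
zero_blooms <- function(grid, n_months) {
  S <- n_water(grid)
  structure(
    list(x = matrix(0, n_months, S),
         severity = rep(0, ceiling(n_months / 12)),
         events = tibble(year = integer(), month = integer(),
                         severe = logical(), centroid_cell = integer(),
                         peak = numeric()),
         background = 0, grid = grid, n_months = as.integer(n_months)),
    class = "rt_blooms"
  )
}

#' Bloom footprint area per year
#'
#' Counts, per year, water cells whose concentration exceeds a
#' mortality-relevant threshold in at least one month.
#'
#' @param blooms An `rt_blooms`.
#' @param threshold Concentration threshold, cells L^-1 (default `1e5`).
#' @return A tibble with `year`, `footprint_cells`.
#' @export
bloom_footprint <- function(blooms, threshold = 1e5) {
  n_years <- ceiling(blooms$n_months / 12)
  purrr::map_dfr(seq_len(n_years), function(yr) {
    rows <- intersect(((yr - 1) * 12 + 1):(yr * 12), seq_len(blooms$n_months))
    tibble(year = yr,
           footprint_cells = sum(apply(blooms$x[rows, , drop = FALSE] > threshold,
                                       2, any)))
  })
}

#' Plot a bloom stack
#'
#' Raster maps of log10 concentration for selected months.
#'
#' @param blooms An `rt_blooms`.
#' @param months Months to draw (default the four highest-concentration
#'   months).
#' @return A ggplot object.
#' @export
plot_blooms <- function(blooms, months = NULL) {
  wc <- water_coords(blooms$grid)
  if (is.null(months)) {
    months <- order(apply(blooms$x, 1, max), decreasing = TRUE)[1:4]
    months <- sort(months)
  }
  dat <- purrr::map_dfr(months, function(t) {
    dplyr::mutate(wc, month = t, log10_conc = log10(pmax(blooms$x[t, ], 1)))
  })
  ggplot2::ggplot(dat, ggplot2::aes(.data$col, -.data$row,
                                    fill = .data$log10_conc)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~month, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = expression(log[10]~cells~L^-1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
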