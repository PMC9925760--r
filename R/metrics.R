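#' Annual ecosystem indicators from a simulation
#'
#' Aggregates a recorded trajectory into the four annual indicators used to
#' describe bloom impacts: total biomass `B_T` (annual mean over months of
#' the domain-mean biomass summed over non-juvenile groups, t km^-2),
#' harvested-group biomass `B_har` (same, harvested groups only), red-tide
#' biomass loss `B_loss` (summed over months within the year, spatially
#' averaged, t km^-2), and total catch `C_T` (summed over fleets, groups
#' and months within the year, spatially averaged, t km^-2 yr^-1).
#'
#' @param run An `rt_run`.
#' @param scenario_id Optional id stored in the output (defaults to the
#'   run's scenario).
#' @return A tibble of class `rt_indicators`: `scenario`, `year`, `B_T`,
#'   `B_har`, `B_loss`, `C_T`.
#' @export
ecosystem_indicators <- function(run, scenario_id = run$scenario) {
  B <- run$B; loss <- run$loss; catch <- run$catch
  g <- run$groups
  keep <- !g$juvenile & g$type != "detritus"
  harv <- keep & g$harvested
  n_months <- dim(B)[1]
  years <- rep(seq_len(ceiling(n_months / 12)), each = 12)[seq_len(n_months)]

  dom <- function(arr, sel) {         # month x 1: domain mean summed groups
    m <- apply(arr[, , sel, drop = FALSE], 1, mean) * sum(sel)
    m
  }
  bt <- tapply(dom(B, keep), years, mean)
  bh <- tapply(dom(B, harv), years, mean)
  bl <- tapply(dom(loss, keep), years, sum)
  ct <- tapply(dom(catch, keep), years, sum)

  out <- tibble(
    scenario = scenario_id,
    year = as.integer(names(bt)),
    B_T = as.numeric(bt), B_har = as.numeric(bh),
    B_loss = as.numeric(bl), C_T = as.numeric(ct)
  )
  class(out) <- c("rt_indicators", class(out))
  out
}

#' Annual red-tide mortality index for one group
#'
#' The year's biomass loss summed over all months and cells, divided by the
#' group's average annual domain biomass (both as domain totals), giving an
#' annual loss rate (yr^-1) comparable to an assessment mortality estimate.
#' Years with zero biomass give `NA`.
#'
#' @param run An `rt_run`.
#' @param group Group name.
#' @return A tibble: `year`, `loss`, `mean_biomass`, `rate`.
#' @export
mortality_index <- function(run, group) {
  i <- match(group, run$groups$group)
  if (is.na(i)) abort(paste("unknown group:", group))
  n_months <- dim(run$B)[1]
  years <- rep(seq_len(ceiling(n_months / 12)), each = 12)[seq_len(n_months)]
  loss_y <- tapply(apply(run$loss[, , i, drop = FALSE], 1, sum), years, sum)
  bio_y <- tapply(apply(run$B[, , i, drop = FALSE], 1, sum), years, mean)
  tibble(
    year = as.integer(names(loss_y)),
    loss = as.numeric(loss_y),
    mean_biomass = as.numeric(bio_y),
    rate = as.numeric(ifelse(bio_y > 0, loss_y / bio_y, NA_real_))
  )
}

#' Annual biomass of trait or taxon communities
#'
#' Sums annual-mean domain-mean biomass over the member groups of each
#' trait (or taxon) class; juvenile groups are excluded. Every non-juvenile
#' group must be mapped to exactly one class.
#'
#' @param run An `rt_run`.
#' @param by `"trait"` or `"taxon"`, or a named character vector mapping
#'   group name to class.
#' @return A tibble: `year`, `class`, `biomass`.
#' @export
community_aggregate <- function(run, by = "trait") {
  g <- run$groups
  map <- if (is.character(by) && length(by) == 1) {
    stopifnot(by %in% c("trait", "taxon"))
    setNames(g[[by]], g$group)
  } else {
    by
  }
  keep <- !g$juvenile
  if (anyNA(map[g$group[keep]])) {
    abort(paste("unmapped group(s):",
                paste(g$group[keep][is.na(map[g$group[keep]])], collapse = ", ")))
  }
  n_months <- dim(run$B)[1]
  years <- rep(seq_len(ceiling(n_months / 12)), each = 12)[seq_len(n_months)]
  series <- apply(run$B, c(1, 3), mean)    # month x group domain means
  purrr::map_dfr(unique(map[g$group[keep]]), function(cl) {
    members <- g$group[keep & map[g$group] == cl]
    s <- if (length(members)) rowSums(series[, members, drop = FALSE]) else
      rep(0, n_months)
    tibble(year = sort(unique(years)), class = cl,
           biomass = as.numeric(tapply(s, years, mean)))
  })
}

#' Screen a scenario ensemble against an assessment loss rate
#'
#' Accepts the scenarios whose focal-year red-tide loss rate falls within
#' 2 standard deviations of an assessment estimate (default 0.77 +/- 0.12)
#' *and* whose RMSE against an observed index falls within a tolerance of
#' the ensemble's minimum RMSE (default 10%).
#'
#' @param runs A data frame with one row per run: `scenario`, `rate`
#'   (focal-year loss rate, yr^-1) and `rmse`.
#' @param mu,sigma Assessment loss rate and its SD.
#' @param k_sigma Half-width of the acceptance band in SDs (default 2).
#' @param rmse_tol Relative RMSE tolerance above the minimum (default 0.1).
#' @return The accepted subset, with logical columns `rate_ok`, `rmse_ok`.
#' @export
screen_scenarios <- function(runs, mu = 0.77, sigma = 0.12, k_sigma = 2,
                             rmse_tol = 0.1) {
  runs <- as_tibble(runs)
  if (!nrow(runs)) abort("empty run set")
  rmse_min <- min(runs$rmse, na.rm = TRUE)
  out <- dplyr::mutate(
    runs,
    rate_ok = abs(.data$rate - mu) <= k_sigma * sigma,
    rmse_ok = .data$rmse <= (1 + rmse_tol) * rmse_min
  )
  dplyr::filter(out, .data$rate_ok & .data$rmse_ok)
}

#' Root-mean-square error between a predicted and an observed index
#'
#' Both series are log-transformed and mean-standardized before comparison
#' (survey indices are relative, so only the shape is scored).
#'
#' @param sim,obs Positive, equal-length series.
#' @return RMSE on the standardized log scale.
#' @export
index_rmse <- function(sim, obs) {
  stopifnot(length(sim) == length(obs), all(sim > 0), all(obs > 0))
  ls <- log(sim) - mean(log(sim))
  lo <- log(obs) - mean(log(obs))
  sqrt(mean((ls - lo)^2))
}

#' Before/after and inside/outside abundance comparison
#'
#' The validation contrast: mean and standard error over cells of the
#' summed biomass of selected groups, for two strata (two cell sets at one
#' time, or one cell set at two times), and the percent change between
#' them (second stratum relative to the first).
#'
#' @param run An `rt_run`.
#' @param groups Group names to sum.
#' @param strata A named list of two strata, each a list with `cells`
#'   (water-cell indices) and `timestep` (recorded month). The first
#'   stratum is the reference ("before" / "outside").
#' @return A tibble with one row per stratum (`stratum`, `n_cells`,
#'   `mean`, `se`) plus the attribute-free column `pct_change` on the
#'   second row (NA on the first; NA also when the reference mean is 0).
#' @export
before_after_in_out <- function(run, groups, strata) {
  stopifnot(length(strata) == 2)
  gi <- match(groups, run$groups$group)
  if (anyNA(gi)) abort("unknown group(s) in comparison")
  vals <- purrr::imap_dfr(strata, function(st, nm) {
    if (!length(st$cells)) abort(paste("empty stratum:", nm))
    v <- apply(run$B[st$timestep, st$cells, gi, drop = FALSE], 2, sum)
    tibble(stratum = nm, n_cells = length(st$cells),
           mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  })
  ref <- vals$mean[1]
  vals$pct_change <- c(NA_real_,
                       if (ref > 0) 100 * (vals$mean[2] - ref) / ref else NA_real_)
  vals
}

#' Plot annual ecosystem indicators
#'
#' @param object An `rt_indicators` tibble (possibly several scenarios
#'   row-bound).
#' @param ... Unused.
#' @return A ggplot: one panel per indicator, one line per scenario.
#' @method autoplot rt_indicators
#' @export
autoplot.rt_indicators <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("B_T", "B_har", "B_loss", "C_T"),
                              names_to = "indicator")
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$value,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "year", y = expression(t~km^-2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Annual domain-mean biomass per group
#'
#' @param run An `rt_run` or `rt_cell_run`.
#' @return A tibble: `year`, `group`, `biomass` (annual mean of the
#'   monthly domain-mean biomass, t km^-2).
#' @export
annual_group_biomass <- function(run) {
  series <- domain_series(run)
  n_months <- nrow(series)
  years <- rep(seq_len(ceiling(n_months / 12)), each = 12)[seq_len(n_months)]
  long <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(series), year = years),
    -"year", names_to = "group", values_to = "biomass"
  )
  dplyr::summarise(dplyr::group_by(long, .data$year, .data$group),
                   biomass = mean(.data$biomass), .groups = "drop")
}
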