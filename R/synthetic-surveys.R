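#' Generate survey-like point observations from a simulated trajectory
#'
#' Samples station-level observed abundances from a simulation: each
#' station sits in a water cell, and its observation equals the local model
#' biomass of the sampled group multiplied by mean-corrected lognormal
#' observation error (`exp(rnorm(0, sigma) - sigma^2/2)`), so the expected
#' observation equals the model biomass and survey means are unbiased
#' estimates of it.
#'
#' @param run An `rt_run` simulation result (see [run_simulation()]).
#' @param design A list with `timesteps` (post-spin-up month indices),
#'   `cells` (water-cell indices to sample from, default all), `groups`
#'   (group names), `n_stations` (stations per timestep), and `sigma`
#'   (lognormal observation SD on the log scale, default 0.3).
#' @param seed Integer seed.
#' @return A tibble: `station`, `timestep`, `cell`, `row`, `col`, `group`,
#'   `observed` (t km^-2).
#' @export
gen_surveys <- function(run, design, seed = 1) {
  withr::local_seed(seed)
  stopifnot(is.list(design), !is.null(design$timesteps), !is.null(design$groups))
  grid <- run$grid
  cells <- design$cells %||% seq_len(n_water(grid))
  if (any(cells < 1 | cells > n_water(grid))) {
    abort("survey design references cells outside the grid")
  }
  n_st <- design$n_stations %||% 30L
  sigma <- design$sigma %||% 0.3
  wc <- water_coords(grid)
  gset <- match(design$groups, run$groups$group)
  if (anyNA(gset)) abort("survey design names unknown groups")

  out <- purrr::map_dfr(design$timesteps, function(t) {
    st_cells <- sample(cells, n_st, replace = length(cells) < n_st)
    purrr::map_dfr(seq_along(gset), function(k) {
      b <- run$B[t, st_cells, gset[k]]
      err <- if (sigma > 0) exp(rnorm(n_st, 0, sigma) - sigma^2 / 2) else 1
      tibble(
        station = seq_len(n_st), timestep = t, cell = st_cells,
        row = wc$row[st_cells], col = wc$col[st_cells],
        group = design$groups[k], observed = b * err
      )
    })
  })
  out
}
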