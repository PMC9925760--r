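#' Write and read a food web as a CSV set
#'
#' The on-disk form is three files: `groups.csv` (one row per group with
#' biomass, rates, tags), `diet.csv` (long: predator, prey, fraction) and
#' `fleets.csv` (fleet, group, catch, price).
#'
#' @param web An `rt_foodweb`.
#' @param dir Directory (created if needed).
#' @return `write_foodweb()` returns `dir` invisibly; `read_foodweb()`
#'   returns the `rt_foodweb` rebuilt (and re-balanced) from the files.
#' @export
write_foodweb <- function(web, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(web$groups, file.path(dir, "groups.csv"))
  diet_long <- as_tibble(as.data.frame.table(web$diet,
                                             responseName = "fraction",
                                             stringsAsFactors = FALSE))
  names(diet_long)[1:2] <- c("predator", "prey")
  readr::write_csv(dplyr::filter(diet_long, .data$fraction > 0),
                   file.path(dir, "diet.csv"))
  readr::write_csv(web$fleets, file.path(dir, "fleets.csv"))
  invisible(dir)
}

#' @rdname write_foodweb
#' @export
read_foodweb <- function(dir) {
  groups <- readr::read_csv(file.path(dir, "groups.csv"),
                            show_col_types = FALSE)
  diet_long <- readr::read_csv(file.path(dir, "diet.csv"),
                               show_col_types = FALSE)
  fleets <- readr::read_csv(file.path(dir, "fleets.csv"),
                            show_col_types = FALSE)
  n <- nrow(groups)
  diet <- matrix(0, n, n, dimnames = list(groups$group, groups$group))
  diet[cbind(match(diet_long$predator, groups$group),
             match(diet_long$prey, groups$group))] <- diet_long$fraction
  solved <- solve_balance(dplyr::select(groups, -"m0base"), diet)
  solved$fleets <- fleets
  solved
}

#' Write a monthly raster stack as long-format CSV
#'
#' One row per (month, row, col): grid origin is the top-left cell,
#' row-major order. Land cells are written with the fill value (0 for
#' bloom concentration, NA for drivers).
#'
#' @param mat `n_months x n_water` matrix of water-cell values.
#' @param grid The `rt_grid`.
#' @param path Output CSV path.
#' @param fill Value written on land cells.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(mat, grid, path, fill = NA_real_) {
  wc <- water_coords(grid)
  full <- tidyr::expand_grid(month = seq_len(nrow(mat)),
                             row = seq_len(grid$n_rows),
                             col = seq_len(grid$n_cols))
  full$value <- fill
  key_w <- paste(wc$row, wc$col)
  m <- match(paste(full$row, full$col), key_w)
  has <- !is.na(m)
  full$value[has] <- mat[cbind(full$month[has], m[has])]
  readr::write_csv(full, path)
  invisible(path)
}

#' Expand water-cell values to a full raster matrix
#'
#' @param values Length-`n_water` vector.
#' @param grid The `rt_grid`.
#' @param fill Value placed on land cells (default 0).
#' @return An `n_rows x n_cols` matrix.
#' @export
as_raster <- function(values, grid, fill = 0) {
  out <- matrix(fill, grid$n_rows, grid$n_cols)
  out[grid$water] <- values
  out
}

#' Read or write a pipeline configuration
#'
#' Configurations are plain YAML mirrors of [default_config()].
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `read_config()` returns the list; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
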