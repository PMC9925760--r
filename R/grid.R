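#' Define a rectangular simulation grid with a land mask
#'
#' Builds the spatial domain used by the simulator: a rectangular raster of
#' square cells, a logical land mask, and the distance from every water cell
#' to the nearest land (shoreline) cell. The grid origin is the top-left
#' (north-west) cell and cells are stored in row-major order.
#'
#' @param n_rows,n_cols Grid dimensions (each at least 2).
#' @param cell_km Cell edge length in km (cell area is `cell_km^2`).
#' @param land Either a logical matrix (`n_rows` x `n_cols`, `TRUE` = land)
#'   or the string `"west"` (default) which makes the first column a
#'   coastline, or `"none"` for an all-water domain bounded by the grid edge.
#'
#' @return An object of class `rt_grid`: a list with `n_rows`, `n_cols`,
#'   `cell_km`, `cell_area` (km^2), `land` (logical matrix),
#'   `coast_distance` (km matrix, `NA` on land, 0 on cells adjacent to the
#'   shoreline), and `water` (integer indices of water cells, row-major).
#' @examples
#' g <- make_grid(6, 8)
#' sum(!g$land)
#' @export
make_grid <- function(n_rows, n_cols, cell_km = 10, land = "west") {
  stopifnot(n_rows >= 2, n_cols >= 2, cell_km > 0)
  if (is.character(land)) {
    land <- match.arg(land, c("west", "none"))
    mask <- matrix(FALSE, n_rows, n_cols)
    if (land == "west") mask[, 1] <- TRUE
  } else {
    mask <- land
    stopifnot(is.logical(mask), all(dim(mask) == c(n_rows, n_cols)))
  }
  if (!any(!mask)) abort("grid must contain at least one water cell")

  coast <- coast_distance_km(mask, cell_km)
  g <- structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_km = cell_km, cell_area = cell_km^2,
      land = mask, coast_distance = coast,
      water = which(t(mask) == FALSE)  # placeholder, replaced below
    ),
    class = "rt_grid"
  )
  # water indices in row-major order over the [row, col] matrix
  rm_order <- order(row(mask)[!mask], col(mask)[!mask])
  g$water <- which(!mask)[rm_order]
  g
}

# Distance (km) from each water cell to the nearest land cell, or to the
# grid edge when the domain has no land. Adjacent-to-shore cells get 0.
coast_distance_km <- function(mask, cell_km) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(NA_real_, nr, nc)
  rr <- row(mask); cc <- col(mask)
  if (any(mask)) {
    lr <- rr[mask]; lc <- cc[mask]
    for (i in which(!mask)) {
      d <- sqrt((rr[i] - lr)^2 + (cc[i] - lc)^2)
      out[i] <- (min(d) - 1) * cell_km
    }
  } else {
    for (i in seq_along(mask)) {
      d <- min(rr[i] - 1, nr - rr[i], cc[i] - 1, nc - cc[i])
      out[i] <- d * cell_km
    }
  }
  out[out < 0] <- 0
  out[mask] <- NA_real_
  out
}

#' @export
print.rt_grid <- function(x, ...) {
  cat("<rt_grid> ", x$n_rows, "x", x$n_cols, " cells of ", x$cell_km,
      " km; ", length(x$water), " water cells\n", sep = "")
  invisible(x)
}

#' Number of water cells in a grid
#' @param grid An `rt_grid`.
#' @return Integer count of water cells.
#' @export
n_water <- function(grid) length(grid$water)

# Row-major linear index helpers for water-cell vectors -----------------

# neighbour index map: for each water cell (position in grid$water), the
# position (again within grid$water) of its rook neighbour in each of the
# four directions, or NA when that neighbour is land or off-grid.
water_neighbours <- function(grid) {
  mask <- grid$land
  nr <- grid$n_rows; nc <- grid$n_cols
  wi <- grid$water
  pos <- matrix(NA_integer_, nr, nc)
  pos[wi] <- seq_along(wi)
  r <- row(mask)[wi]; c <- col(mask)[wi]
  nb <- function(dr, dc) {
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    out <- rep(NA_integer_, length(wi))
    out[ok] <- pos[cbind(r2[ok], c2[ok])]
    out
  }
  list(N = nb(-1, 0), S = nb(1, 0), W = nb(0, -1), E = nb(0, 1))
}

# tidy coordinates of water cells
water_coords <- function(grid) {
  wi <- grid$water
  tibble(
    cell = seq_along(wi),
    row = row(grid$land)[wi],
    col = col(grid$land)[wi],
    coast_km = grid$coast_distance[wi]
  )
}
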