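#' Habitat-capacity-weighted biomass movement
#'
#' Donor-controlled dispersal on the rook (4-neighbour) lattice with
#' reflecting boundaries: the fraction of a cell's biomass that emigrates
#' in a month scales with `min(0.95, D * dt / cell_km) * (1 - capacity)`,
#' so well-suited cells lose nothing and poor cells shed biomass; the flux
#' over each of the four lattice edges is weighted by the receiving
#' neighbour's capacity and normalised by the full stencil size, which
#' makes a uniform field under uniform capacity exactly neutral. Land and
#' grid edges are no-flux boundaries and total biomass is conserved
#' exactly.
#'
#' @param B Biomass over water cells (vector, t km^-2).
#' @param capacity Habitat capacity over water cells, in (0, 1\].
#' @param D Dispersal rate, km yr^-1.
#' @param grid The `rt_grid`.
#' @param nb Precomputed [water_neighbours()] map (recomputed if `NULL`).
#' @param dt_months Step length in months.
#' @return The updated biomass vector.
#' @export
movement_step <- function(B, capacity, D, grid, nb = NULL, dt_months = 1) {
  stopifnot(all(B >= 0), all(capacity > 0), D >= 0)
  if (is.null(nb)) nb <- water_neighbours(grid)
  frac <- min(0.95, D * (dt_months / 12) / grid$cell_km)

  # per-edge flux i -> j: B_i * frac * (1 - cap_i) * cap_j / 4; summing the
  # received parcels over edges conserves mass exactly, and a uniform field
  # under uniform capacity receives exactly what it sheds
  B_new <- B
  send <- B * frac * (1 - capacity) / 4
  for (k in seq_along(nb)) {
    d <- nb[[k]]
    ok <- !is.na(d)
    give <- send[ok] * capacity[d[ok]]
    B_new[ok] <- B_new[ok] - give
    B_new[d[ok]] <- B_new[d[ok]] + give
  }
  B_new
}

#' Gravity-model allocation of fishing effort
#'
#' Distributes a fleet's fixed total effort across water cells in
#' proportion to profitability: the price-weighted biomass of its target
#' groups minus the spatial cost of fishing the cell, floored at zero.
#' When no cell is profitable the effort is spread uniformly.
#'
#' @param B `S x n` biomass matrix over water cells.
#' @param price Length-`n` price vector for the fleet (0 for non-targets).
#' @param cost Length-`S` spatial cost (>= 0), e.g. distance to port.
#' @param total Total effort to allocate (default `S`, i.e. a baseline
#'   mean effort density of 1 per cell).
#' @return Length-`S` effort vector summing to `total`.
#' @export
allocate_effort <- function(B, price, cost = 0, total = nrow(B)) {
  S <- nrow(B)
  profit <- pmax(0, as.numeric(B %*% price) - cost)
  if (sum(profit) <= 0) rep(total / S, S) else total * profit / sum(profit)
}

#' Run the gridded spatiotemporal simulation
#'
#' The full spatial model: per-cell foraging-arena trophic dynamics plus
#' capacity-weighted movement, gravity-model effort allocation, red-tide
#' forcing, and a spin-up. The per-month order of operations is fixed:
#' (1) update drivers and habitat capacity (environmental responses times
#' the scenario's sublethal foraging multiplier), (2) apply red-tide
#' mortality — remove `loss = A * B` from every targeted group, record it,
#' and route it to the detritus pool, (3) trophic-dynamics sub-steps,
#' (4) movement, (5) effort reallocation and catch accounting (effort used
#' in step 3 is reallocated from the current biomass field each month).
#'
#' During the spin-up months the bloom forcing is off and each group's
#' domain total is relaxed toward the mass-balance baseline with a
#' 6-month time constant; recording starts after spin-up.
#'
#' A stability screen aborts (class `rt_instability`) if any biomass is
#' non-finite or any group's domain total leaves
#' `[1e-4, 100] x` baseline.
#'
#' @param model An `rt_model` ([calibrate_model()]).
#' @param grid An `rt_grid`.
#' @param drivers An `rt_drivers` covering `spinup_months + n_months`
#'   months (cycled if shorter), or `NULL` for the neutral environment.
#' @param blooms An `rt_blooms` with `n_months` months (spin-up months are
#'   unforced), or `NULL` for no forcing.
#' @param scenario One row of [build_scenario_grid()], or `NULL` for the
#'   baseline (no red tide) run.
#' @param n_months Recorded months.
#' @param spinup_months Spin-up length (default 24).
#' @param env_responses An `rt_env_responses`
#'   ([default_env_responses()]) or `NULL` for capacity 1.
#' @param cost Spatial fishing-cost vector over water cells (default 0).
#' @param n_substeps Euler sub-steps per month.
#' @param record_capacity Keep the capacity tensor (default TRUE).
#' @return An `rt_run`: list with arrays `B`, `loss`, `catch`
#'   (`n_months x S x n`, t km^-2; catch is the month's removal),
#'   optionally `capacity`, plus `catch_fleet`
#'   (`n_months x fleets x n`, domain mean), `groups`, `grid`, `scenario`
#'   id, and `baseline_total` (domain biomass at the mass-balance state).
#' @export
run_simulation <- function(model, grid, drivers = NULL, blooms = NULL,
                           scenario = NULL, n_months = 36,
                           spinup_months = 24, env_responses = NULL,
                           cost = 0, n_substeps = 4,
                           record_capacity = TRUE) {
  n <- model$n
  S <- n_water(grid)
  gnames <- model$groups$group
  nb <- water_neighbours(grid)
  if (!is.null(blooms)) stopifnot(blooms$n_months >= n_months)
  chl_ref <- if (!is.null(drivers)) drivers$baseline[["chlorophyll"]] else 1

  fns <- if (!is.null(scenario)) scenario_functions(scenario) else NULL
  targeted <- forcing_targets(model, scenario)

  B <- matrix(model$B0, S, n, byrow = TRUE)
  B0_tot <- model$B0 * S
  eff <- matrix(1, max(1, length(model$fleet_names)), S)

  rec <- function() array(0, c(n_months, S, n), dimnames = list(NULL, NULL, gnames))
  Brec <- rec(); loss_rec <- rec(); catch_rec <- rec()
  cap_rec <- if (record_capacity) rec() else NULL
  catch_fleet <- array(0, c(n_months, length(model$fleet_names), n),
                       dimnames = list(NULL, model$fleet_names, gnames))

  total_months <- spinup_months + n_months
  for (tm in seq_len(total_months)) {
    spinup <- tm <= spinup_months
    t_rec <- tm - spinup_months
    # during spin-up, cycle drivers over their first year; afterwards align
    # driver/bloom month to the recorded clock
    drv_m <- if (is.null(drivers)) NULL else if (spinup) {
      ((tm - 1) %% 12) + 1
    } else min(t_rec, drivers$n_months)

    x <- if (!spinup && !is.null(blooms)) blooms$x[t_rec, ] else NULL

    # (1) capacity
    cap <- matrix(1, S, n)
    for (i in seq_len(n)) {
      fv <- 1
      if (!is.null(x) && targeted[i] && !is.null(fns$foraging)) {
        fv <- foraging_capacity(x, fns$foraging)
      }
      resp <- if (!is.null(env_responses)) env_responses[[gnames[i]]] else list()
      cap[, i] <- if (is.null(drivers) || length(resp) == 0) {
        pmax(1e-4, 1 * fv)
      } else {
        capacity_field(drivers, drv_m, resp, fv)
      }
    }

    # (2) red-tide kill
    if (!is.null(x) && !is.null(fns)) {
      A <- mortality_proportion(x, fns$mortality)
      if (any(A > 0)) {
        kill <- B * (A %o% as.numeric(targeted))
        B <- B - kill
        if (length(model$det)) {
          B[, model$det[1]] <- B[, model$det[1]] + rowSums(kill)
        }
        loss_rec[t_rec, , ] <- kill
      }
    }

    # (3) trophic dynamics
    chl <- if (is.null(drivers)) rep(chl_ref, S) else
      drivers$vars$chlorophyll[drv_m, ]
    F_mat <- if (length(model$fleet_names)) {
      t(eff) %*% model$q   # S x n: effort density times catchability
    } else matrix(0, S, n)
    dt <- (1 / 12) / n_substeps
    catch_m <- matrix(0, S, n)
    for (k in seq_len(n_substeps)) {
      out <- dyn_substep(B, model, cap, chl, chl_ref, F_mat, matrix(0, S, n), dt)
      B <- out$B
      catch_m <- catch_m + out$catch
    }
    if (any(!is.finite(B))) {
      abort(sprintf("non-finite biomass at month %d", tm),
            class = "rt_instability")
    }

    # (4) movement
    for (i in seq_len(n)) {
      if (model$dispersal[i] > 0) {
        B[, i] <- movement_step(B[, i], cap[, i], model$dispersal[i],
                                grid, nb)
      }
    }

    # spin-up nudging: relax domain totals toward baseline (tau = 6 months)
    if (spinup) {
      tot <- colSums(B)
      fac <- ifelse(tot > 0, (B0_tot / tot)^(1 / 6), 1)
      B <- sweep(B, 2, fac, `*`)
    } else {
      tot <- colSums(B)
      bad <- tot > 100 * B0_tot | tot < 1e-4 * B0_tot
      if (any(bad)) {
        abort(paste0("unstable run: domain biomass of ",
                     paste(gnames[bad], collapse = ", "),
                     " left [1e-4, 100] x baseline at month ", t_rec),
              class = "rt_instability")
      }
      Brec[t_rec, , ] <- B
      catch_rec[t_rec, , ] <- catch_m
      if (record_capacity) cap_rec[t_rec, , ] <- cap
    }

    # (5) effort reallocation for next month
    if (length(model$fleet_names)) {
      for (f in seq_along(model$fleet_names)) {
        eff[f, ] <- allocate_effort(B, model$price[f, ], cost = cost,
                                    total = S)
      }
    }
  }

  # per-fleet catch: apportion each group's cell catch by fleet share of F
  if (length(model$fleet_names)) {
    Fshare <- model$q / rep(pmax(colSums(model$q), 1e-300),
                            each = nrow(model$q))
    for (f in seq_along(model$fleet_names)) {
      for (i in seq_len(n)) {
        if (model$q[f, i] > 0) {
          catch_fleet[, f, i] <- apply(catch_rec[, , i, drop = FALSE], 1, mean) *
            Fshare[f, i]
        }
      }
    }
  }

  structure(
    list(B = Brec, loss = loss_rec, catch = catch_rec,
         capacity = cap_rec, catch_fleet = catch_fleet,
         groups = model$groups, grid = grid,
         scenario = if (is.null(scenario)) "baseline" else scenario$scenario,
         baseline_total = B0_tot, n_months = n_months,
         spinup_months = spinup_months),
    class = "rt_run"
  )
}

#' @export
print.rt_run <- function(x, ...) {
  cat("<rt_run> scenario ", x$scenario, ": ", x$n_months, " months x ",
      dim(x$B)[2], " cells x ", dim(x$B)[3], " groups\n", sep = "")
  invisible(x)
}

#' Tidy a simulation trajectory
#'
#' @param x An `rt_run`.
#' @param ... Unused.
#' @return A tibble `month`, `cell`, `group`, `biomass`, `loss`, `catch`.
#' @method tidy rt_run
#' @export
tidy.rt_run <- function(x, ...) {
  dims <- dim(x$B)
  grd <- expand.grid(month = seq_len(dims[1]), cell = seq_len(dims[2]),
                     group = dimnames(x$B)[[3]],
                     stringsAsFactors = FALSE)
  tibble(
    month = grd$month, cell = grd$cell, group = grd$group,
    biomass = as.numeric(x$B), loss = as.numeric(x$loss),
    catch = as.numeric(x$catch)
  )
}

#' @rdname tidy.rt_run
#' @method glance rt_run
#' @export
glance.rt_run <- function(x, ...) {
  tibble(
    scenario = x$scenario,
    n_months = x$n_months,
    n_cells = dim(x$B)[2],
    n_groups = dim(x$B)[3],
    total_loss = sum(x$loss),
    final_total_biomass = sum(x$B[x$n_months, , ])
  )
}

#' Monthly domain-mean biomass per group
#'
#' @param run An `rt_run` or `rt_cell_run`.
#' @return A `n_months x n_groups` matrix of spatial means (t km^-2).
#' @export
domain_series <- function(run) {
  if (inherits(run, "rt_cell_run")) return(run$B)
  apply(run$B, c(1, 3), mean)
}
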