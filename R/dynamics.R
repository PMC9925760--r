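#' Foraging-arena consumption flow
#'
#' Consumption of prey by a predator under foraging-arena theory: prey
#' exchange between an invulnerable pool and a foraging arena at rate `v`,
#' where they are taken at effective search rate `a * capacity`:
#' \deqn{Q = \frac{a' v B_{prey} B_{pred}}{2 v + a' B_{pred}}, \qquad
#'       a' = a \cdot capacity,}
#' so the flow is bounded by the arena supply `v * B_prey` and tends to the
#' mass-action rate `a' B_prey B_pred / 2` as `v` grows. The predator's
#' habitat capacity scales the search rate (a smaller arena in poor
#' habitat).
#'
#' At the model level the exchange rate for a link is
#' `v = m * Q0 / B_prey0` with `m > 1` the predator's unitless
#' vulnerability multiplier (2 is the mixed default; low `m` gives
#' donor control, high `m` top-down control), and `a` is calibrated so the
#' Ecopath baseline flow `Q0 = B_pred * QB * DC` is reproduced exactly at
#' baseline biomasses and capacity 1.
#'
#' @param B_prey,B_pred Biomasses, t km^-2 (vectorised).
#' @param a Search rate (calibrated).
#' @param v Arena exchange rate.
#' @param capacity Predator habitat capacity in (0, 1\].
#' @return Flow in t km^-2 yr^-1.
#' @examples
#' consumption(0, 5, a = 1, v = 2)      # no prey, no flow
#' @export
consumption <- function(B_prey, B_pred, a, v, capacity = 1) {
  stopifnot(all(B_prey >= 0), all(B_pred >= 0), all(v > 0))
  aeff <- a * capacity
  aeff * v * B_prey * B_pred / (2 * v + aeff * B_pred)
}

#' Producer production rate under a chlorophyll forcing
#'
#' Primary production is the baseline rate `pb * B` scaled by the relative
#' chlorophyll anomaly, clipped to \[0.1, 10\], and by habitat capacity;
#' at baseline chlorophyll and capacity 1 production equals `pb * B`.
#'
#' @param B Producer biomass, t km^-2.
#' @param chlorophyll Local chlorophyll.
#' @param capacity Habitat capacity in (0, 1\].
#' @param pb Baseline production/biomass, yr^-1.
#' @param baseline Baseline chlorophyll (anomaly reference).
#' @return Production, t km^-2 yr^-1.
#' @export
producer_growth <- function(B, chlorophyll, capacity = 1, pb, baseline = 1) {
  stopifnot(all(chlorophyll >= 0))
  f <- pmin(10, pmax(0.1, chlorophyll / baseline))
  pb * B * f * capacity
}

#' Attach calibrated dynamic rates to a balanced food web
#'
#' Derives every rate the time-dynamic model needs from the static
#' snapshot: per-link arena exchange rates and search rates (calibrated so
#' the Ecopath baseline is an exact equilibrium), growth efficiencies
#' (`pb/qb`, constant), baseline fishing mortalities and fleet
#' catchabilities, and the detritus inflow/export closure.
#'
#' @param web An `rt_foodweb` from [gen_foodweb()] or [solve_balance()].
#' @param v_mult Per-predator vulnerability multipliers (> 1): a single
#'   value or a named vector keyed by group name; default 2 for every
#'   predator (mixed trophic control).
#' @param dispersal_mult Per-group multipliers on the trait-based dispersal
#'   rates (named vector or single value, default 1).
#' @return An `rt_model`: the web plus matrices `Q0`, `v_rate`, `a`,
#'   vectors `ge`, `F0`, `m0base`, a `q` catchability matrix
#'   (fleet x group), detritus closure rates, and the resolved `v_mult`
#'   and `dispersal` vectors.
#' @export
calibrate_model <- function(web, v_mult = 2, dispersal_mult = 1) {
  g <- web$groups
  n <- nrow(g)
  vm <- resolve_named(v_mult, g$group, default = 2)
  if (any(vm <= 1)) abort("vulnerability multipliers must exceed 1")
  dm <- resolve_named(dispersal_mult, g$group, default = 1)

  Q0 <- web$diet * (g$biomass * g$qb)        # [pred, prey]
  Bprey <- matrix(g$biomass, n, n, byrow = TRUE)
  Bpred <- matrix(g$biomass, n, n)
  M <- matrix(vm, n, n)                      # per-predator multiplier
  v_rate <- ifelse(Q0 > 0, M * Q0 / Bprey, 0)
  a <- ifelse(Q0 > 0, 2 * M * Q0 / (Bprey * Bpred * (M - 1)), 0)

  cons <- g$type == "consumer"
  ge <- ifelse(cons, g$pb / pmax(g$qb, 1e-12), 0)
  F0 <- ifelse(g$biomass > 0, g$catch / g$biomass, 0)

  fleets <- web$fleets %||%
    tibble(fleet = character(), group = character(), catch = numeric(),
           price = numeric())
  fl_names <- unique(fleets$fleet)
  q <- matrix(0, length(fl_names), n, dimnames = list(fl_names, g$group))
  price <- q
  for (k in seq_len(nrow(fleets))) {
    i <- match(fleets$group[k], g$group)
    q[fleets$fleet[k], i] <- q[fleets$fleet[k], i] +
      fleets$catch[k] / g$biomass[i]
    price[fleets$fleet[k], i] <- fleets$price[k]
  }

  det <- which(g$type == "detritus")
  u <- web$unassimilated
  det_in0 <- sum(g$m0base * g$biomass) + u * sum(g$biomass * g$qb)
  det_pred0 <- if (length(det)) sum(Q0[, det]) else 0
  det_export <- if (length(det) && g$biomass[det[1]] > 0) {
    max(0, det_in0 - det_pred0) / g$biomass[det[1]]
  } else 0

  structure(
    list(
      web = web, groups = g, diet = web$diet, n = n,
      Q0 = Q0, v_rate = v_rate, a = a,
      ge = ge, F0 = F0, m0base = g$m0base,
      q = q, price = price, fleet_names = fl_names,
      v_mult = vm, dispersal = g$dispersal * dm,
      det = det, unassimilated = u, det_export = det_export,
      is_cons = cons, is_prod = g$type == "producer",
      B0 = g$biomass
    ),
    class = "rt_model"
  )
}

resolve_named <- function(x, names, default) {
  out <- rep(default, length(names))
  names(out) <- names
  if (is.null(names(x))) {
    if (length(x) == 1) out[] <- x else {
      stopifnot(length(x) == length(names)); out[] <- x
    }
  } else {
    bad <- setdiff(names(x), names)
    if (length(bad)) abort(paste("unknown group(s):", paste(bad, collapse = ", ")))
    out[names(x)] <- x
  }
  out
}

# One Euler sub-step of the trophic dynamics for S cells at once.
# B, cap, m0mult, F: S x n matrices; chl: length-S vector (raw values);
# dt in years. Returns B_new, catch (S x n, biomass removed this sub-step)
# and the per-group budget components (rates scaled by the loss cap).
dyn_substep <- function(B, cal, cap, chl, chl_ref, F_mat, m0mult, dt) {
  S <- nrow(B); n <- cal$n
  gains <- matrix(0, S, n)
  pred_loss <- matrix(0, S, n)
  det_gain <- numeric(S)

  for (j in which(cal$is_cons)) {
    prey <- which(cal$Q0[j, ] > 0)
    if (!length(prey)) next
    Bj <- B[, j]
    aeff <- matrix(cal$a[j, prey], S, length(prey), byrow = TRUE) * cap[, j]
    vr <- matrix(cal$v_rate[j, prey], S, length(prey), byrow = TRUE)
    Q <- aeff * vr * B[, prey, drop = FALSE] * Bj / (2 * vr + aeff * Bj)
    pred_loss[, prey] <- pred_loss[, prey] + Q
    qtot <- rowSums(Q)
    gains[, j] <- gains[, j] + cal$ge[j] * qtot
    det_gain <- det_gain + cal$unassimilated * qtot
  }
  for (i in which(cal$is_prod)) {
    # density-dependent P/B (production saturates at twice the baseline
    # flow as biomass grows, the usual primary-production closure), equal
    # to the Ecopath P/B at baseline biomass
    pb_eff <- cal$groups$pb[i] * 2 / (1 + B[, i] / cal$B0[i])
    gains[, i] <- gains[, i] +
      producer_growth(B[, i], chl, cap[, i], pb_eff, chl_ref)
  }

  m0_loss <- sweep(B, 2, cal$m0base, `*`) * (1 + m0mult)
  fish_loss <- F_mat * B
  losses <- pred_loss + m0_loss + fish_loss
  if (length(cal$det)) {
    d <- cal$det[1]
    gains[, d] <- gains[, d] + rowSums(m0_loss) + det_gain
    losses[, d] <- losses[, d] + cal$det_export * B[, d]
    m0_loss[, d] <- 0
  }

  # semi-implicit (Patankar) update: gains explicit, losses implicit via
  # their rates, so biomass stays positive and the mass-balance state is
  # an exact fixed point at any step size (fast pools such as detritus
  # and phytoplankton turn over at >> 48 yr^-1, where a fully explicit
  # step would be unstable)
  loss_rate <- ifelse(B > 0, losses / B, 0)
  B_new <- (B + dt * gains) / (1 + dt * loss_rate)
  # realized losses are rate x updated biomass: Delta B = dt (G - R B_new)
  scale <- ifelse(B > 0, B_new / B, 0)

  list(B = B_new, catch = fish_loss * scale * dt,
       gains = gains, pred = pred_loss * scale, fish = fish_loss * scale,
       m0 = m0_loss * scale)
}

#' Advance a single well-mixed cell by one month
#'
#' Integrates the biomass dynamics of one cell over a month with explicit
#' Euler sub-steps:
#' \deqn{\dot B_i = g_i - \sum_j Q_{ji} - M0_{base,i}(1 + mult_i) B_i - F_i B_i,}
#' where the growth term \eqn{g_i} is the growth efficiency times total
#' consumption for consumers and [producer_growth()] for producers; the
#' detritus pool receives all other-mortality losses and the unassimilated
#' fraction of consumption and loses detritivory and export. Per-sub-step
#' losses are capped at available biomass.
#'
#' @param state A list (CellState): `B` named biomass vector, and optional
#'   `m0mult` (additional other-mortality multipliers, default 0),
#'   `capacity` (default 1), `effort` (per-fleet effort multipliers,
#'   default 1), `chlorophyll` (default the baseline).
#' @param model An `rt_model` from [calibrate_model()].
#' @param dt_months Length of the step in months (default 1).
#' @param n_substeps Euler sub-steps per month (default 4).
#' @param chl_baseline Baseline chlorophyll reference.
#' @return The updated state (same shape), with `catch` (biomass removed
#'   by fishing over the step, per group) attached.
#' @export
step_cell <- function(state, model, dt_months = 1, n_substeps = 4,
                      chl_baseline = 1) {
  n <- model$n
  B <- matrix(state$B, 1, n)
  cap <- matrix(state$capacity %||% rep(1, n), 1, n)
  m0m <- matrix(state$m0mult %||% rep(0, n), 1, n)
  eff <- state$effort %||% setNames(rep(1, length(model$fleet_names)),
                                    model$fleet_names)
  F_mat <- matrix(if (length(model$fleet_names)) colSums(model$q * eff) else
    rep(0, n), 1, n)
  chl <- state$chlorophyll %||% chl_baseline
  dt <- (dt_months / 12) / n_substeps
  catch <- numeric(n)
  if (any(!is.finite(B))) abort("non-finite biomass", class = "rt_instability")
  for (k in seq_len(n_substeps)) {
    out <- dyn_substep(B, model, cap, chl, chl_baseline, F_mat, m0m, dt)
    B <- out$B
    catch <- catch + out$catch[1, ]
    if (any(!is.finite(B))) abort("non-finite biomass", class = "rt_instability")
  }
  state$B <- setNames(B[1, ], model$groups$group)
  state$catch <- setNames(catch, model$groups$group)
  state
}

#' Run the single-cell (well-mixed) dynamics for many months
#'
#' The non-spatial reference trajectory: one homogeneous cell stepped with
#' [step_cell()], optionally under bloom forcing evaluated exactly as the
#' spatial engine does (monthly kill `A * B` removed and routed to
#' detritus, sublethal multiplier on capacity).
#'
#' @param model An `rt_model`.
#' @param n_months Months to simulate.
#' @param x Optional per-month bloom concentration vector (cells L^-1).
#' @param scenario Optional one-row scenario (see [build_scenario_grid()]).
#' @param n_substeps Euler sub-steps per month.
#' @return An `rt_cell_run`: list with `B` (`n_months x n` matrix of
#'   start-of-month-after-update biomass), `loss`, `catch` matrices, and
#'   `groups`.
#' @export
run_cell <- function(model, n_months, x = NULL, scenario = NULL,
                     n_substeps = 4) {
  n <- model$n
  gnames <- model$groups$group
  B <- model$B0
  Bt <- matrix(NA_real_, n_months, n, dimnames = list(NULL, gnames))
  loss <- Bt; loss[] <- 0
  catch <- Bt; catch[] <- 0
  targeted <- forcing_targets(model, scenario)
  fns <- if (!is.null(scenario)) scenario_functions(scenario) else NULL

  for (t in seq_len(n_months)) {
    cap <- rep(1, n)
    if (!is.null(fns) && !is.null(x) && x[t] > 0) {
      A <- mortality_proportion(x[t], fns$mortality)
      kill <- ifelse(targeted, A * B, 0)
      B <- B - kill
      if (length(model$det)) B[model$det[1]] <- B[model$det[1]] + sum(kill)
      loss[t, ] <- kill
      if (!is.null(fns$foraging)) {
        fv <- foraging_capacity(x[t], fns$foraging)
        cap <- ifelse(targeted, pmax(1e-4, fv), 1)
      }
    }
    st <- step_cell(list(B = B, capacity = cap), model,
                    n_substeps = n_substeps)
    B <- st$B
    Bt[t, ] <- B
    catch[t, ] <- st$catch
  }
  structure(list(B = Bt, loss = loss, catch = catch, groups = model$groups),
            class = "rt_cell_run")
}

# logical vector: which groups a scenario forces
forcing_targets <- function(model, scenario) {
  if (is.null(scenario)) return(rep(FALSE, model$n))
  if (scenario$target == "all_consumers") model$is_cons
  else model$groups$group == scenario$target_group & model$is_cons
}
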