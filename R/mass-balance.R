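#' Solve the food-web mass-balance identity for missing parameters
#'
#' For every living group \eqn{i} the static snapshot must satisfy
#' \deqn{B_i PB_i EE_i = \sum_j B_j QB_j DC_{ji} + Y_i + BA_i,}
#' i.e. production equals predation plus catch plus biomass accumulation,
#' with the unconsumed remainder flowing to "other mortality"
#' \eqn{M0_{base,i} = PB_i (1 - EE_i)}. Exactly one of `biomass` or `ee`
#' may be `NA` per living group; the resulting system is linear in the
#' unknowns and is solved directly.
#'
#' The detritus group is a non-living pool: it receives every group's other
#' mortality plus an unassimilated fraction of all consumption, and its
#' ecotrophic efficiency is the fraction of that inflow consumed by
#' detritivores (the remainder is exported/buried).
#'
#' @param groups A data frame with one row per group and columns `group`,
#'   `type` (`"producer"`, `"consumer"` or `"detritus"`), `biomass`
#'   (t km^-2), `pb` (production/biomass, yr^-1), `qb`
#'   (consumption/biomass, yr^-1; 0 for producers and detritus), `ee`
#'   (ecotrophic efficiency), `catch` (total fisheries removal,
#'   t km^-2 yr^-1) and optionally `ba` (biomass accumulation, default 0).
#' @param diet Square numeric matrix, predators in rows and prey in
#'   columns (dimnames = group names); each consumer row sums to 1.
#' @param unassimilated Fraction of consumption egested to detritus
#'   (default 0.2, the conventional Ecopath value).
#'
#' @return An `rt_foodweb`: a list with the completed `groups` tibble
#'   (including `m0base`), the `diet` matrix, `unassimilated`, and detritus
#'   bookkeeping (`det_inflow`, `det_ee`). Errors if any solved EE falls
#'   outside \[0, 1\] (the offending groups are named, not clipped).
#' @seealso [check_balance()]
#' @examples
#' gr <- tibble::tibble(
#'   group = c("phyto", "grazer"), type = c("producer", "consumer"),
#'   biomass = c(10, 1), pb = c(100, 10), qb = c(0, 50),
#'   ee = NA_real_, catch = 0
#' )
#' dc <- matrix(c(0, 0, 1, 0), 2, 2, dimnames = list(gr$group, gr$group))
#' solve_balance(gr, dc)$groups$ee[1]  # 0.05
#' @export
solve_balance <- function(groups, diet, unassimilated = 0.2) {
  groups <- as_tibble(groups)
  if (!"ba" %in% names(groups)) groups$ba <- 0
  n <- nrow(groups)
  stopifnot(all(dim(diet) == n))
  living <- groups$type != "detritus"
  cons <- groups$type == "consumer"

  rs <- rowSums(diet[cons, , drop = FALSE])
  if (any(abs(rs - 1) > 1e-8)) {
    abort(paste0("diet fractions must sum to 1 for every consumer; off: ",
                 paste(groups$group[cons][abs(rs - 1) > 1e-8], collapse = ", ")))
  }

  unk_b <- living & is.na(groups$biomass)
  unk_e <- living & is.na(groups$ee)
  if (any(unk_b & unk_e)) {
    abort("each living group may have exactly one unknown among biomass and ee")
  }
  # detritus: biomass must be given; EE is derived, not solved
  det <- which(!living)
  if (any(is.na(groups$biomass[det]))) abort("detritus biomass must be given")

  idx_l <- which(living)
  m <- length(idx_l)
  unknown_of <- integer(0)        # column index per living group
  kind <- character(0)
  ucol <- rep(NA_integer_, n)
  for (i in idx_l) {
    if (unk_b[i] || unk_e[i]) {
      unknown_of <- c(unknown_of, i)
      kind <- c(kind, if (unk_b[i]) "B" else "EE")
      ucol[i] <- length(unknown_of)
    }
  }
  nu <- length(unknown_of)

  B <- groups$biomass; PB <- groups$pb; QB <- groups$qb; EE <- groups$ee
  Y <- groups$catch; BA <- groups$ba

  if (nu > 0) {
    A <- matrix(0, m, nu)
    rhs <- numeric(m)
    for (k in seq_len(m)) {
      i <- idx_l[k]
      # equation: B_i PB_i EE_i - sum_j B_j QB_j DC[j,i] - Y_i - BA_i = 0
      const <- -Y[i] - BA[i]
      if (!is.na(ucol[i]) && kind[ucol[i]] == "EE") {
        A[k, ucol[i]] <- A[k, ucol[i]] + B[i] * PB[i]
      } else if (!is.na(ucol[i]) && kind[ucol[i]] == "B") {
        A[k, ucol[i]] <- A[k, ucol[i]] + PB[i] * EE[i]
      } else {
        const <- const + B[i] * PB[i] * EE[i]
      }
      for (j in seq_len(n)) {
        dc <- diet[j, i]
        if (dc == 0 || QB[j] == 0) next
        if (!is.na(ucol[j]) && kind[ucol[j]] == "B") {
          A[k, ucol[j]] <- A[k, ucol[j]] - QB[j] * dc
        } else {
          const <- const - B[j] * QB[j] * dc
        }
      }
      rhs[k] <- -const
    }
    # m equations (one per living group), nu unknowns; rows for groups with
    # no unknown must already balance — solve the square subsystem of rows
    # that contain an unknown, then check all residuals via check_balance.
    has_u <- vapply(seq_len(m), function(k) any(A[k, ] != 0), logical(1))
    Ak <- A[has_u, , drop = FALSE]; rk <- rhs[has_u]
    if (nrow(Ak) < nu) abort("singular balance system: fewer informative equations than unknowns")
    sol <- tryCatch(qr.solve(Ak, rk), error = function(e) abort("singular balance system"))
    for (u in seq_len(nu)) {
      i <- unknown_of[u]
      if (kind[u] == "B") B[i] <- sol[u] else EE[i] <- sol[u]
    }
  }

  bad <- idx_l[EE[idx_l] < -1e-9 | EE[idx_l] > 1 + 1e-9]
  if (length(bad)) {
    abort(paste0("unbalanced web: EE outside [0, 1] for ",
                 paste(sprintf("%s (EE = %.3f)", groups$group[bad], EE[bad]),
                       collapse = ", ")))
  }
  EE[idx_l] <- pmin(pmax(EE[idx_l], 0), 1)
  if (any(B[idx_l] < 0)) abort("unbalanced web: negative solved biomass")

  groups$biomass <- B
  groups$ee <- EE
  groups$m0base <- ifelse(living, groups$pb * (1 - groups$ee), 0)

  # detritus inflow = other-mortality losses + egestion
  q_tot <- B * QB                       # total consumption per predator
  det_in <- sum(groups$m0base[living] * B[living]) + unassimilated * sum(q_tot)
  det_pred <- vapply(det, function(i) sum(B * QB * diet[, i]), numeric(1))
  det_ee <- if (length(det) && det_in > 0) sum(det_pred) / det_in else 0
  if (length(det)) groups$ee[det] <- det_ee
  if (det_ee > 1 + 1e-9) {
    abort(sprintf("unbalanced web: detritus consumption exceeds inflow (EE = %.3f)", det_ee))
  }

  structure(
    list(groups = groups, diet = diet, unassimilated = unassimilated,
         det_inflow = det_in, det_ee = min(det_ee, 1)),
    class = "rt_foodweb"
  )
}

#' Audit the mass-balance identity of a fully specified food web
#'
#' Recomputes, independently of the solver, the per-group residual
#' production − (predation + catch + accumulation + other mortality),
#' which is zero for a balanced web.
#'
#' @param web An `rt_foodweb` (or a list with `groups` and `diet` in the
#'   same layout).
#' @param tolerance Absolute residual above which a group is flagged.
#' @return A tibble with `group`, `production`, `predation`, `catch`,
#'   `ba`, `other_mortality`, `residual`, `balanced`.
#' @export
check_balance <- function(web, tolerance = 1e-9) {
  g <- web$groups
  diet <- web$diet
  living <- g$type != "detritus"
  pred_on <- vapply(seq_len(nrow(g)),
                    function(i) sum(g$biomass * g$qb * diet[, i]),
                    numeric(1))
  prod <- ifelse(living, g$biomass * g$pb, 0)
  other <- ifelse(living, g$m0base * g$biomass, 0)
  res <- ifelse(living, prod - (pred_on + g$catch + g$ba + other), 0)
  tibble(
    group = g$group,
    production = prod,
    predation = pred_on,
    catch = g$catch,
    ba = g$ba,
    other_mortality = other,
    residual = res,
    balanced = abs(res) <= tolerance
  )
}

#' @export
print.rt_foodweb <- function(x, ...) {
  g <- x$groups
  cat("<rt_foodweb> ", nrow(g), " groups (",
      sum(g$type == "producer"), " producer, ",
      sum(g$type == "consumer"), " consumer, ",
      sum(g$type == "detritus"), " detritus)\n", sep = "")
  print(g, ...)
  invisible(x)
}

#' @rdname solve_balance
#' @param x An `rt_foodweb`.
#' @param ... Unused.
#' @method tidy rt_foodweb
#' @export
tidy.rt_foodweb <- function(x, ...) x$groups

#' @rdname solve_balance
#' @method glance rt_foodweb
#' @export
glance.rt_foodweb <- function(x, ...) {
  g <- x$groups
  living <- g$type != "detritus"
  tibble(
    n_groups = nrow(g),
    n_consumers = sum(g$type == "consumer"),
    total_biomass = sum(g$biomass[living]),
    total_production = sum(g$biomass[living] * g$pb[living]),
    total_catch = sum(g$catch),
    max_ee = max(g$ee[living]),
    detritus_ee = x$det_ee
  )
}
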