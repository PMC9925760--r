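#' Percent bias between a simulated and a reference series
#'
#' The hydrological convention:
#' \deqn{pbias = 100 \cdot \frac{\sum_t (sim_t - ref_t)}{\sum_t ref_t}.}
#'
#' @param sim,ref Equal-length numeric series; `ref` must not sum to 0.
#' @return Percent bias (signed).
#' @examples
#' pbias(1.1 * (1:5), 1:5)  # +10
#' @export
pbias <- function(sim, ref) {
  stopifnot(length(sim) == length(ref))
  if (sum(ref) == 0) abort("all-zero reference series")
  100 * sum(sim - ref) / sum(ref)
}

#' Total absolute percent bias over groups
#'
#' The calibration score: the sum over groups of `|pbias|` between the
#' simulated and reference per-group series.
#'
#' @param sim,ref `n_months x n_groups` matrices (matching columns).
#' @return Total absolute percent bias.
#' @export
total_pbias <- function(sim, ref) {
  stopifnot(all(dim(sim) == dim(ref)))
  sum(vapply(seq_len(ncol(ref)), function(i) abs(pbias(sim[, i], ref[, i])),
             numeric(1)))
}

#' Lognormal log-likelihood of a reference series given a simulation
#'
#' \deqn{LL = \sum_t \log \phi\left(\frac{\ln ref_t - \ln sim_t}{\sigma}\right)
#'        / \sigma,} maximal when the simulation matches the reference.
#' Tracked as a diagnostic alongside percent bias; not optimized.
#'
#' @param sim,ref Positive equal-length series.
#' @param sigma Lognormal observation SD (log scale), default 0.3.
#' @return The log-likelihood.
#' @export
loglik <- function(sim, ref, sigma = 0.3) {
  stopifnot(length(sim) == length(ref))
  if (any(sim <= 0) || any(ref <= 0)) abort("series must be positive")
  sum(dnorm(log(ref), mean = log(sim), sd = sigma, log = TRUE))
}

#' One-at-a-time parameter sensitivity screen
#'
#' Perturbs each parameter by the configured factors (default x2 and
#' x0.5), reruns the simulator, and ranks parameters by the largest
#' absolute change in total percent bias against the reference. Runs that
#' go unstable score the worst-rank penalty and are flagged.
#'
#' @param runner A function `(params) -> n_months x n_groups` biomass
#'   matrix, where `params` is a named numeric vector.
#' @param params Named numeric vector of incumbent parameter values
#'   (names like `"v:groupname"` and `"D:groupname"`).
#' @param ref Reference biomass matrix (same shape as the runner output).
#' @param factors Perturbation factors (default `c(2, 0.5)`).
#' @return A tibble ranked by decreasing sensitivity: `parameter`,
#'   `sensitivity` (max |delta total pbias|), `unstable`, `rank`.
#' @export
oat_sensitivity <- function(runner, params, ref, factors = c(2, 0.5)) {
  base <- runner(params)
  base_score <- total_pbias(base, ref)
  rows <- purrr::imap_dfr(params, function(val, nm) {
    deltas <- vapply(factors, function(f) {
      p <- params; p[nm] <- val * f
      out <- tryCatch(total_pbias(runner(p), ref),
                      rt_instability = function(e) NA_real_)
      abs(out - base_score)
    }, numeric(1))
    tibble(parameter = nm,
           sensitivity = if (all(is.na(deltas))) NA_real_ else
             max(deltas, na.rm = TRUE),
           unstable = anyNA(deltas))
  })
  worst <- max(c(rows$sensitivity, 0), na.rm = TRUE)
  rows$sensitivity[is.na(rows$sensitivity)] <- -Inf
  rows <- dplyr::arrange(rows, dplyr::desc(.data$sensitivity))
  rows$sensitivity[!is.finite(rows$sensitivity)] <- NA_real_
  rows$rank <- seq_len(nrow(rows))
  rows
}

#' Candidate grids for the iterative fit
#'
#' Vulnerability multipliers are searched on a log-spaced grid over
#' \[1.01, 1e4\] and dispersal-rate multipliers over \[0.1, 10\].
#'
#' @param kind `"v"` or `"D"`.
#' @param n Number of candidates (default 20).
#' @return Numeric candidate vector.
#' @export
candidate_grid <- function(kind, n = 20) {
  switch(kind,
    v = exp(seq(log(1.01), log(1e4), length.out = n)),
    D = exp(seq(log(0.1), log(10), length.out = n)),
    abort(paste("unknown parameter kind:", kind))
  )
}

param_kind <- function(nm) sub(":.*$", "", nm)

#' Iterative one-at-a-time calibration by percent bias
#'
#' The fitting loop: parameters are visited in ranked order; each is
#' iterated over its candidate grid and the value with the lowest total
#' absolute percent bias is retained (ties broken toward the value closest
#' to the incumbent, in log space). The pass repeats until an iteration
#' accepts no change, or `max_iter` is reached; the score trajectory is
#' non-increasing by construction. The log-likelihood of every candidate
#' is recorded as a diagnostic.
#'
#' @inheritParams oat_sensitivity
#' @param ranked Character vector of parameter names in the order to visit
#'   (e.g. from [oat_sensitivity()]); defaults to `names(params)`.
#' @param n_candidates Candidate-grid size per parameter (default 20).
#' @param max_iter Maximum number of full passes.
#' @param sigma Lognormal SD for the diagnostic log-likelihood.
#' @return An `rt_calibration`: list with `params` (fitted named vector),
#'   `score` (final total |pbias|), `initial_score`, `iterations`,
#'   `records` (tibble of every evaluated candidate: `iteration`,
#'   `parameter`, `candidate`, `pbias_total`, `ll`, `accepted`).
#' @export
iterate_fit <- function(runner, params, ref, ranked = names(params),
                        n_candidates = 20, max_iter = 10, sigma = 0.3) {
  eval_p <- function(p) {
    tryCatch({
      sim <- runner(p)
      ll <- sum(vapply(seq_len(ncol(ref)), function(i) {
        loglik(pmax(sim[, i], 1e-12), pmax(ref[, i], 1e-12), sigma)
      }, numeric(1)))
      list(score = total_pbias(sim, ref), ll = ll)
    }, rt_instability = function(e) list(score = Inf, ll = -Inf))
  }
  score_of <- function(p) eval_p(p)$score

  incumbent <- params
  score <- score_of(incumbent)
  initial_score <- score
  records <- list()
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    improved <- FALSE
    for (nm in ranked) {
      grid <- candidate_grid(param_kind(nm), n_candidates)
      best_val <- incumbent[nm]; best_score <- score
      cand_rows <- purrr::map_dfr(grid, function(v) {
        p <- incumbent; p[nm] <- v
        ev <- eval_p(p)
        tibble(iteration = iter, parameter = nm, candidate = v,
               pbias_total = ev$score, ll = ev$ll, accepted = FALSE)
      })
      eps <- 1e-10
      better <- which(cand_rows$pbias_total < best_score - eps)
      if (length(better)) {
        minv <- min(cand_rows$pbias_total[better])
        tied <- better[cand_rows$pbias_total[better] <= minv + eps]
        pick <- tied[which.min(abs(log(cand_rows$candidate[tied]) -
                                     log(incumbent[nm])))]
        best_val <- cand_rows$candidate[pick]
        best_score <- cand_rows$pbias_total[pick]
        cand_rows$accepted[pick] <- TRUE
        incumbent[nm] <- best_val
        score <- best_score
        improved <- TRUE
      }
      records[[length(records) + 1]] <- cand_rows
    }
    if (!improved) break
  }

  structure(
    list(params = incumbent, score = score, initial_score = initial_score,
         iterations = iter,
         records = dplyr::bind_rows(records)),
    class = "rt_calibration"
  )
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat("<rt_calibration> ", x$iterations, " iterations; total |pbias| ",
      format(x$initial_score, digits = 4), " -> ",
      format(x$score, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname iterate_fit
#' @param x An `rt_calibration`.
#' @param ... Unused.
#' @method tidy rt_calibration
#' @export
tidy.rt_calibration <- function(x, ...) x$records

#' @rdname iterate_fit
#' @method glance rt_calibration
#' @export
glance.rt_calibration <- function(x, ...) {
  tibble(
    iterations = x$iterations,
    initial_pbias = x$initial_score,
    final_pbias = x$score,
    n_evaluations = nrow(x$records),
    n_accepted = sum(x$records$accepted)
  )
}

#' Build a simulator runner over vulnerability and dispersal parameters
#'
#' Wraps [run_simulation()] as a pure function of a named parameter vector
#' (`"v:<group>"` vulnerability multipliers, `"D:<group>"` dispersal
#' multipliers) returning the monthly domain-mean biomass matrix of the
#' living groups — the interface [oat_sensitivity()] and [iterate_fit()]
#' consume. A scaled-down stand-in for the production ensemble runner.
#'
#' @param web An `rt_foodweb`.
#' @param grid,drivers,blooms,scenario,n_months,spinup_months,env_responses
#'   Passed to [run_simulation()].
#' @param n_substeps Euler sub-steps per month.
#' @return A function `(params) -> n_months x n_living matrix`.
#' @export
make_runner <- function(web, grid, drivers = NULL, blooms = NULL,
                        scenario = NULL, n_months = 24, spinup_months = 12,
                        env_responses = NULL, n_substeps = 4) {
  living <- web$groups$type != "detritus"
  function(params) {
    v <- params[param_kind(names(params)) == "v"]
    d <- params[param_kind(names(params)) == "D"]
    names(v) <- sub("^v:", "", names(v))
    names(d) <- sub("^D:", "", names(d))
    v <- pmax(v, 1.01)          # clamp to the searchable domain
    d <- pmax(d, 0)
    model <- calibrate_model(web,
                             v_mult = if (length(v)) v else 2,
                             dispersal_mult = if (length(d)) d else 1)
    run <- run_simulation(model, grid, drivers = drivers, blooms = blooms,
                          scenario = scenario, n_months = n_months,
                          spinup_months = spinup_months,
                          env_responses = env_responses,
                          n_substeps = n_substeps, record_capacity = FALSE)
    domain_series(run)[, living, drop = FALSE]
  }
}

#' Plot the calibration score trajectory
#'
#' @param object An `rt_calibration`.
#' @param ... Unused.
#' @return A ggplot of the best total |pbias| at the end of each iteration.
#' @method autoplot rt_calibration
#' @export
autoplot.rt_calibration <- function(object, ...) {
  rec <- object$records
  traj <- rec |>
    dplyr::filter(.data$accepted) |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(score = min(.data$pbias_total), .groups = "drop")
  traj <- dplyr::bind_rows(
    tibble(iteration = 0L, score = object$initial_score), traj
  )
  ggplot2::ggplot(traj, ggplot2::aes(.data$iteration, .data$score)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "total |pbias| (%)") +
    ggplot2::theme_minimal()
}
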