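#' Generate a balanced synthetic food web
#'
#' Draws a small coastal-shelf-style food web — one primary producer, one
#' detritus pool, and a ladder of consumers spanning planktivores to top
#' predators — with rates on realistic magnitudes (producer P/B of order
#' 10^2 yr^-1, top-predator P/B below 1 yr^-1, gross growth efficiency
#' 0.1–0.25), then solves the mass-balance identity for every group's
#' ecotrophic efficiency. Draws whose solved EE leaves \[0, 0.95\], or whose
#' per-link consumption exceeds the foraging-arena supply bound, are
#' rejected and redrawn (bounded retries).
#'
#' Each group carries a habitat trait (upper/lower trophic level pelagic,
#' demersal, reef-associated, benthic invertebrate, producer, detritus), a
#' taxon tag, a harvested flag, and a dispersal rate assigned by the
#' "300-30-3" rule (300 km yr^-1 pelagic, 30 km yr^-1 demersal and
#' reef-associated, 3 km yr^-1 benthic/planktonic). The highest-trophic-
#' level harvested consumer is tagged as the focal group (`focal = TRUE`)
#' and named `"grouper"`; single-target scenarios and the population
#' screening use it.
#'
#' @param n_groups Total number of groups including producer and detritus
#'   (>= 4).
#' @param n_fleets Number of fishing fleets (>= 1); every fleet lands a
#'   positive catch of at least one group.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param max_redraws Rejection-sampling budget before the configuration is
#'   declared infeasible.
#' @return An `rt_foodweb` (see [solve_balance()]) whose `groups` tibble
#'   additionally has `trait`, `taxon`, `harvested`, `juvenile`, `focal`,
#'   `dispersal` (km yr^-1), and a `fleets` tibble (`fleet`, `group`,
#'   `catch`, `price`).
#' @examples
#' web <- gen_foodweb(n_groups = 8, n_fleets = 2, seed = 1)
#' all(check_balance(web)$balanced)
#' @export
gen_foodweb <- function(n_groups = 10, n_fleets = 2, seed = 1,
                        max_redraws = 60) {
  stopifnot(n_groups >= 4, n_fleets >= 1)
  withr::local_seed(seed)

  for (try in seq_len(max_redraws)) {
    web <- try(draw_foodweb(n_groups, n_fleets), silent = TRUE)
    if (!inherits(web, "try-error")) return(web)
  }
  abort(paste0("infeasible food-web configuration: no balanced draw in ",
               max_redraws, " attempts (", attr(web, "condition")$message, ")"))
}

# one candidate draw; errors when it cannot balance
draw_foodweb <- function(n_groups, n_fleets) {
  n_cons <- n_groups - 2
  # trophic levels: consumers spread over [2, 4.5]
  tl_cons <- if (n_cons == 1) 2 else 2 + 2.5 * (seq_len(n_cons) - 1) / (n_cons - 1)
  tl <- c(1, tl_cons, 1)  # producer, consumers, detritus
  type <- c("producer", rep("consumer", n_cons), "detritus")
  names <- c("phytoplankton",
             consumer_names(n_cons),
             "detritus")

  # biomass declines ~ one order of magnitude per trophic level
  b0 <- 60 * exp(rnorm(1, 0, 0.2))
  biomass <- b0 * 0.12^(tl - 1) * exp(rnorm(n_groups, 0, 0.25))
  biomass[type == "detritus"] <- 30 * exp(rnorm(1, 0, 0.2))

  pb <- 120 * 0.22^(tl - 1) * exp(rnorm(n_groups, 0, 0.15))
  pb[type == "detritus"] <- 0
  ge <- runif(n_groups, 0.12, 0.25)            # gross growth efficiency
  qb <- ifelse(type == "consumer", pb / ge, 0)

  # diet: each consumer eats groups 0.5-2 TL below it; detritus available
  # to low-TL consumers
  diet <- matrix(0, n_groups, n_groups, dimnames = list(names, names))
  for (j in which(type == "consumer")) {
    lower <- which(tl < tl[j] - 0.4 & seq_len(n_groups) != j & type != "detritus")
    if (!length(lower)) lower <- 1L
    w <- exp(-abs(tl[lower] - (tl[j] - 1))) * runif(length(lower), 0.3, 1)
    frac_det <- if (tl[j] < 2.6) runif(1, 0.1, 0.4) else 0
    diet[j, lower] <- (1 - frac_det) * w / sum(w)
    diet[j, n_groups] <- frac_det
  }

  # traits by trophic level and a pelagic/demersal coin flip
  trait <- character(n_groups)
  trait[type == "producer"] <- "producer"
  trait[type == "detritus"] <- "detritus"
  for (j in which(type == "consumer")) {
    trait[j] <- if (tl[j] >= 3.2) {
      sample(c("upper TL pelagic", "demersal", "reef-associated"), 1,
             prob = c(0.4, 0.3, 0.3))
    } else {
      sample(c("lower TL pelagic", "benthic invertebrate", "demersal"), 1,
             prob = c(0.5, 0.3, 0.2))
    }
  }
  taxon <- ifelse(type == "producer", "phytoplankton",
           ifelse(type == "detritus", "detritus",
           ifelse(tl >= 4.2, sample(c("fishes", "elasmobranchs"), n_groups, TRUE,
                                    prob = c(0.7, 0.3)),
           ifelse(trait == "benthic invertebrate",
                  sample(c("benthic invertebrates", "cephalopods"), n_groups, TRUE,
                         prob = c(0.7, 0.3)),
                  "fishes"))))
  dispersal <- dispersal_300_30_3(trait)

  # fisheries: fleets target mid-to-high TL consumers; exploitation
  # F = phi * PB with phi in 0.05-0.2 keeps EE feasible
  cons_idx <- which(type == "consumer")
  targetable <- cons_idx[tl[cons_idx] >= 2.3]
  if (!length(targetable)) targetable <- cons_idx
  fleet_rows <- list()
  catch <- numeric(n_groups)
  for (f in seq_len(n_fleets)) {
    k <- max(1L, ceiling(length(targetable) / n_fleets))
    tg <- sample(targetable, min(k, length(targetable)))
    phi <- runif(length(tg), 0.05, 0.2)
    y <- phi * pb[tg] * biomass[tg]
    catch[tg] <- catch[tg] + y
    fleet_rows[[f]] <- tibble(fleet = sprintf("fleet%02d", f),
                              group = names[tg], catch = y, price = 1)
  }
  fleets <- dplyr::bind_rows(fleet_rows)

  groups <- tibble(
    group = names, type = type, tl = tl,
    biomass = biomass, pb = pb, qb = qb,
    ee = ifelse(type == "detritus", NA_real_, NA_real_),
    catch = catch, ba = 0,
    trait = trait, taxon = taxon,
    harvested = catch > 0, juvenile = FALSE,
    dispersal = dispersal
  )
  groups$ee[groups$type == "detritus"] <- 0  # derived by solve_balance

  web <- solve_balance(groups, diet)
  g <- web$groups
  living <- g$type != "detritus"
  if (any(g$ee[living] > 0.95)) abort("EE above 0.95")
  if (web$det_ee > 0.95) abort("detritus EE above 0.95")

  focal <- which(living & g$harvested)
  focal <- focal[which.max(g$tl[focal])]
  g$focal <- seq_len(nrow(g)) == focal
  g$group[focal] <- "grouper"
  rownames(web$diet) <- colnames(web$diet) <- g$group
  fleets$group[fleets$group == groups$group[focal]] <- "grouper"
  web$groups <- g
  web$fleets <- fleets
  web
}

# baseline consumption flows Q0[j, i] = B_j QB_j DC[j, i]
baseline_flows <- function(web) {
  g <- web$groups
  web$diet * (g$biomass * g$qb)
}

consumer_names <- function(n) {
  base <- c("zooplankton", "benthic_inverts", "forage_fish", "shrimp",
            "small_demersals", "reef_fish", "mackerel", "snapper",
            "coastal_sharks", "king_mackerel", "groupers", "tunas")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("consumer%02d", seq_len(n - length(base))))
}

#' Dispersal rates from habitat traits ("300-30-3" rule)
#'
#' @param trait Character vector of habitat traits.
#' @return km yr^-1: 300 for pelagic traits, 30 for demersal and
#'   reef-associated, 3 for benthic invertebrates, producers and detritus.
#' @export
dispersal_300_30_3 <- function(trait) {
  dplyr::case_match(trait,
    c("upper TL pelagic", "lower TL pelagic") ~ 300,
    c("demersal", "reef-associated") ~ 30,
    c("benthic invertebrate", "producer", "detritus") ~ 3,
    .default = 30
  )
}
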