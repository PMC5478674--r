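clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# species argument normaliser: "grass" -> 1L etc.
species_code <- function(species) {
  if (is.character(species)) {
    code <- SPECIES_CODES[species]
    if (anyNA(code)) stop("unknown species: ",
                          paste(species[is.na(code)], collapse = ", "),
                          call. = FALSE)
    as.integer(code)
  } else as.integer(species)
}

# content shift: out[i, j] = m[i - dr, j - dc]; zero fill when open
shift_mat <- function(m, dr, dc, periodic) {
  nr <- nrow(m); nc <- ncol(m)
  if (periodic) {
    ri <- ((seq_len(nr) - 1L - dr) %% nr) + 1L
    ci <- ((seq_len(nc) - 1L - dc) %% nc) + 1L
    m[ri, ci, drop = FALSE]
  } else {
    out <- matrix(0, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    if (length(rs) > 0 && length(cs) > 0 && rs[1] <= rs[length(rs)])
      out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
}

# per-cell sum of m over the Chebyshev ring at distance k
ring_sum <- function(m, k, periodic) {
  out <- matrix(0, nrow(m), ncol(m))
  d <- -k:k
  offs <- rbind(cbind(-k, d), cbind(k, d),
                cbind(d[-c(1, length(d))], -k),
                cbind(d[-c(1, length(d))], k))
  for (i in seq_len(nrow(offs)))
    out <- out + shift_mat(m, -offs[i, 1], -offs[i, 2], periodic)
  out
}

# signed shell interaction (facilitation > 0) and its shell 1-2 part,
# computed for every cell at once
interaction_fields <- function(grid, config) {
  periodic <- identical(grid$boundary, "periodic")
  bmax <- spp_par(config, "b_max")
  Bnorm <- pathway_biomass(grid$species, grid$growth, config) / bmax[3]
  w <- config$kernel$shell_weights
  ones <- matrix(1, grid$height, grid$width)
  I <- matrix(0, grid$height, grid$width)
  F12 <- I
  for (k in seq_along(w)) {
    cnt <- if (periodic) 8 * k else pmax(ring_sum(ones, k, periodic), 1)
    rm_ <- ring_sum(Bnorm, k, periodic) / cnt
    I <- I + w[k] * rm_
    if (k <= 2) F12 <- F12 + max(w[k], 0) * rm_
  }
  list(interaction = I, facilitation = F12)
}

#' Moisture-driven growth increment
#'
#' Growth-unit change of a plant in response to one season's precipitation:
#' a full unit (+1) at or above the species optimum, a proportional fraction
#' between the species' harsh threshold and optimum, and a loss (down to -1
#' at zero rainfall) below the harsh threshold, moving the plant back down
#' its growth pathway.
#'
#' @param species species names or integer codes (vectorised; 0 = bare
#'   gives 0).
#' @param season_precip seasonal precipitation total (mm), scalar.
#' @param config model configuration.
#' @return growth-unit delta(s) in \[-1, 1\].
#' @export
#' @examples
#' moisture_growth_increment("grass", 60)  # at optimum: +1
#' moisture_growth_increment("grass", 0)   # harsh: loses growth
moisture_growth_increment <- function(species, season_precip,
                                      config = default_config()) {
  sp <- species_code(species)
  stopifnot(length(season_precip) == 1, season_precip >= 0)
  harsh <- spp_par(config, "precip_harsh")
  opt <- spp_par(config, "precip_opt")
  out <- numeric(length(sp))
  occ <- sp > 0L
  h <- harsh[sp[occ]]; o <- opt[sp[occ]]
  out[occ] <- ifelse(season_precip >= o, 1,
              ifelse(season_precip >= h, (season_precip - h) / (o - h),
                     -(h - season_precip) / h))
  dim(out) <- dim(sp)
  out
}

# species suitability of a season's rainfall, in [0, 1]
moisture_suitability <- function(season_precip, config) {
  harsh <- spp_par(config, "precip_harsh")
  opt <- spp_par(config, "precip_opt")
  clamp((season_precip - harsh) / (opt - harsh))
}

#' Neighbourhood interaction stress
#'
#' Signed plant-plant interaction summed over the five concentric shells:
#' per-shell mean neighbour biomass (normalised by the largest species
#' maximum) weighted by the kernel's signed shell weights (facilitation
#' close in, competition further out), then squashed through a logistic to a
#' stress in \[0, 1\]. An empty neighbourhood gives the neutral stress 0.5.
#'
#' @param grid an `ecodune_grid`.
#' @param cell `c(row, col)` of an occupied cell.
#' @param config model configuration.
#' @param sensitivity scaling of the felt interaction (the seasonal update
#'   uses `1 - sens_slope * biomass / b_max(tree)`, so large plants barely
#'   feel their neighbours while seedlings and grasses feel them fully).
#' @return stress in \[0, 1\].
#' @export
neighbourhood_stress <- function(grid, cell, config = default_config(),
                                 sensitivity = 1) {
  sh <- shells(grid, cell, n_shells = length(config$kernel$shell_weights))
  bmax <- spp_par(config, "b_max")
  w <- config$kernel$shell_weights
  I <- 0
  for (k in seq_along(w)) {
    ring <- sh[[k]]
    if (nrow(ring) == 0) next
    b <- pathway_biomass(grid$species[ring], grid$growth[ring], config)
    I <- I + w[k] * sum(b / bmax[3]) / nrow(ring)
  }
  unname(plogis(-config$kernel$squash_rate * I * sensitivity))
}

#' Sediment-balance stress
#'
#' Stress from net seasonal sand-height change at a plant's cell: zero at
#' zero net change, rising quadratically with burial or exposure and
#' saturating at 1 at the species tolerance.
#'
#' @param cell_sand_delta net slab change over the season (signed).
#' @param species species name or code (vectorised with `cell_sand_delta`).
#' @param config model configuration.
#' @return stress in \[0, 1\].
#' @export
sediment_balance_stress <- function(cell_sand_delta, species,
                                    config = default_config()) {
  sp <- species_code(species)
  tol <- spp_par(config, "sed_tol_slabs")
  unname(clamp((abs(cell_sand_delta) / tol[sp])^2))
}

# age stress: ramps 0 -> 1 over the last quartile of the species lifespan
age_stress <- function(age, species, config) {
  life <- spp_par(config, "lifespan_seasons")
  out <- numeric(length(species))
  occ <- species > 0L
  L <- life[species[occ]]
  out[occ] <- clamp((age[occ] - 0.75 * L) / (0.25 * L))
  dim(out) <- dim(species)
  out
}

#' Compound stress to mortality probability
#'
#' Combines the seven stress components (neighbourhood, precipitation,
#' biomass, age, sediment balance, grazing, fire) as a weighted arithmetic
#' mean, then squashes the result through a normalised logistic onto a
#' seasonal mortality probability with background floor `p0`: all-zero
#' stress gives `p0`, all-one stress gives 1, and the probability is
#' monotone non-decreasing in every component.
#'
#' @param components numeric length 7, each in \[0, 1\] (order:
#'   neighbourhood, precipitation, biomass, age, sediment, grazing, fire).
#' @param weights non-negative weights summing to 1 (default from config).
#' @param config model configuration.
#' @return mortality probability in \[0, 1\].
#' @export
#' @examples
#' compound_stress(rep(0, 7))  # background mortality p0
#' compound_stress(rep(1, 7))  # certain death
compound_stress <- function(components, weights = NULL,
                            config = default_config()) {
  if (is.null(weights)) weights <- config$stress$weights
  check_weights(weights, length(components), "stress weights")
  if (any(components < -1e-12) || any(components > 1 + 1e-12))
    stop("stress components must lie in [0, 1]", call. = FALSE)
  S <- sum(weights * clamp(components))
  p0 <- config$stress$p0
  p0 + (1 - p0) * logistic01(S, config$stress$squash_rate)
}

#' Seasonal vegetation update
#'
#' The synchronous once-per-season vegetation transition: every occupant is
#' evaluated against the start-of-season state (so the result is independent
#' of cell iteration order). Each plant (i) accrues the seven-component
#' compound stress and dies with the resulting probability (plants past
#' their species lifespan die outright), (ii) if it survives, ages one
#' season and gains or loses growth units per the moisture response; cells
#' that were bare at the start of the season recruit with a probability
#' increasing in moisture suitability and local shell 1-2 facilitation,
#' with species drawn from a grass-biased prior on bare ground and a
#' neighbour-copying mixture otherwise, both modulated by each species'
#' moisture suitability.
#'
#' Afterwards the per-season bookkeeping is reset: the sediment-balance
#' reference is set to the current sand surface and the grazing and fire
#' stress markers are cleared.
#'
#' @param grid an `ecodune_grid`.
#' @param season_precip this season's precipitation total (mm).
#' @param config model configuration.
#' @param draws optional list of pre-drawn uniform matrices (`die`, `rec`,
#'   `spc`), used by order-independence oracles; drawn from the global RNG
#'   when omitted.
#' @return The updated grid (clock not advanced; drivers do that).
#' @export
vegetation_step <- function(grid, season_precip, config = default_config(),
                            draws = NULL) {
  stopifnot(length(season_precip) == 1, is.finite(season_precip),
            season_precip >= 0)
  nr <- grid$height; nc <- grid$width
  sp <- grid$species
  occ <- sp > 0L
  if (is.null(draws)) {
    draws <- list(die = matrix(runif(nr * nc), nr, nc),
                  rec = matrix(runif(nr * nc), nr, nc),
                  spc = matrix(runif(nr * nc), nr, nc))
  }

  fields <- interaction_fields(grid, config)
  bmax <- spp_par(config, "b_max")
  B <- pathway_biomass(sp, grid$growth, config)
  # big plants exert interaction but barely feel it; small plants feel it
  sens <- clamp(1 - config$kernel$sens_slope * B / bmax[3])
  s_nb <- plogis(-config$kernel$squash_rate * fields$interaction * sens)

  harsh <- spp_par(config, "precip_harsh")
  opt <- spp_par(config, "precip_opt")
  gmax <- spp_par(config, "g_max")
  life <- spp_par(config, "lifespan_seasons")

  s_pre <- matrix(0, nr, nc)
  s_pre[occ] <- 1 - clamp((season_precip - harsh[sp[occ]]) /
                            (opt[sp[occ]] - harsh[sp[occ]]))
  s_bio <- matrix(0, nr, nc)
  s_bio[occ] <- 1 - B[occ] / bmax[sp[occ]]
  s_age <- age_stress(grid$age, sp, config)
  s_sed <- matrix(0, nr, nc)
  delta_sand <- grid$sand - grid$sand_ref
  tol <- spp_par(config, "sed_tol_slabs")
  s_sed[occ] <- clamp((abs(delta_sand[occ]) / tol[sp[occ]])^2)
  s_grz <- clamp(grid$graze_stress)
  s_fire <- matrix(0, nr, nc)
  s_fire[occ & grid$fire_flag > 0L] <- 1

  w <- config$stress$weights
  check_weights(w, 7, "stress weights")
  S <- w[1] * s_nb + w[2] * s_pre + w[3] * s_bio + w[4] * s_age +
    w[5] * s_sed + w[6] * s_grz + w[7] * s_fire
  p0 <- config$stress$p0
  p_die <- p0 + (1 - p0) * logistic01(clamp(S), config$stress$squash_rate)
  p_die[occ & grid$age >= life[pmax(sp, 1L)]] <- 1
  dies <- occ & (draws$die < p_die)
  surv <- occ & !dies

  delta_g <- moisture_growth_increment(sp, season_precip, config)
  growth <- grid$growth
  growth[surv] <- clamp(grid$growth[surv] + delta_g[surv],
                        0, gmax[sp[surv]])
  age <- grid$age
  age[surv] <- grid$age[surv] + 1L

  # recruitment into cells bare at the start of the season
  suit <- moisture_suitability(season_precip, config)
  rc <- config$recruitment
  p_rec <- clamp(rc$r_base + rc$r_moisture * max(suit) +
                   rc$r_facilitation * pmax(fields$facilitation, 0))
  recruits <- (!occ) & (draws$rec < p_rec)

  periodic <- identical(grid$boundary, "periodic")
  cnt <- lapply(1:3, function(k) {
    ind <- (sp == k) + 0
    ring_sum(ind, 1, periodic) + ring_sum(ind, 2, periodic)
  })
  tot <- cnt[[1]] + cnt[[2]] + cnt[[3]]
  blend <- rc$copy_blend
  # burned ground recruits like bare soil (pioneer, grass-biased prior
  # rather than copying the fire-survivor pool) until it is recolonised
  bare_like <- tot == 0 | grid$pioneer > 0L
  wsp <- lapply(1:3, function(k) {
    copy_frac <- ifelse(tot > 0, cnt[[k]] / pmax(tot, 1), 0)
    base <- ifelse(bare_like, rc$bare_prior[[k]],
                   (1 - blend) * copy_frac + blend * rc$bare_prior[[k]])
    base * (suit[k] + rc$suit_floor)
  })
  wtot <- wsp[[1]] + wsp[[2]] + wsp[[3]]
  u <- draws$spc * wtot
  choice <- 1L + (u >= wsp[[1]]) + (u >= wsp[[1]] + wsp[[2]])

  sp_new <- sp
  sp_new[dies] <- 0L
  growth[dies] <- 0
  age[dies] <- 0L
  sp_new[recruits] <- choice[recruits]
  growth[recruits] <- 1
  age[recruits] <- 0L

  grid$species <- sp_new
  grid$growth <- growth
  grid$age <- age
  grid$pioneer[recruits] <- 0L
  grid$fire_flag <- matrix(0L, nr, nc)
  grid$graze_stress <- matrix(0, nr, nc)
  grid$sand_ref <- grid$sand
  grid
}
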