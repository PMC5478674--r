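#' Disturbance regime
#'
#' Bundles a fire-return interval and a grazing stocking rate. Named levels
#' follow typical Kalahari rangeland practice: fire `"low"` = once every 10
#' years, `"medium"` = 5, `"high"` = 2 (or `"none"`); grazing `"low"` =
#' 0.001, `"medium"` = 0.01, `"high"` = 0.06 LSU (large stock units) per
#' hectare, or any non-negative number.
#'
#' @param fire `"none"`, `"low"`, `"medium"`, `"high"` or an interval in
#'   years (>= 1).
#' @param grazing `"low"`, `"medium"`, `"high"` or a stocking rate
#'   (LSU ha^-1, >= 0).
#' @return A list of class `disturbance_regime` with `fire_interval`
#'   (years, `Inf` for none) and `stocking_rate`.
#' @export
disturbance_regime <- function(fire = "none", grazing = 0) {
  fire_interval <-
    if (is.character(fire))
      switch(match.arg(fire, c("none", "low", "medium", "high")),
             none = Inf, low = 10, medium = 5, high = 2)
    else as.numeric(fire)
  if (is.finite(fire_interval) && fire_interval < 1)
    stop("fire interval must be >= 1 year (or 'none')", call. = FALSE)
  stocking <-
    if (is.character(grazing))
      switch(match.arg(grazing, c("low", "medium", "high")),
             low = 0.001, medium = 0.01, high = 0.06)
    else as.numeric(grazing)
  if (!is.finite(stocking) || stocking < 0)
    stop("stocking rate must be a non-negative number", call. = FALSE)
  structure(list(fire_interval = fire_interval, stocking_rate = stocking),
            class = "disturbance_regime")
}

#' Is a fire due this season?
#'
#' Fires occur as a single domain-wide probabilistic event in the late dry
#' season (SON by default), in years spaced by the regime's fire-return
#' interval counted from `start_year`.
#'
#' @param clock a grid clock (`list(year, season, ...)`).
#' @param regime a [disturbance_regime()].
#' @param start_year first year of the run (fires fall on
#'   `start_year + k * interval`).
#' @param config model configuration (`fire$season`).
#' @return `TRUE` if a fire event happens this season.
#' @export
#' @examples
#' r <- disturbance_regime(fire = "high")
#' fire_due(list(year = 1962, season = "SON"), r, 1960)  # TRUE
fire_due <- function(clock, regime, start_year,
                     config = default_config()) {
  if (!is.finite(regime$fire_interval)) return(FALSE)
  clock$season == config$fire$season &&
    (clock$year - start_year) %% regime$fire_interval == 0
}

#' Apply a fire event
#'
#' Each occupied cell burns independently with a species-specific
#' probability (grasses most flammable, trees least). Burned occupants are
#' removed and the cell is marked with a fire-stress flag that feeds the
#' following season's compound stress before being cleared.
#'
#' @param grid an `ecodune_grid`.
#' @param config model configuration (`species$*$burn_prob`).
#' @return list with the updated `grid` and `burned` (cell count).
#' @export
apply_fire <- function(grid, config = default_config()) {
  occ <- grid$species > 0L
  if (!any(occ)) return(list(grid = grid, burned = 0L))
  bp <- spp_par(config, "burn_prob")
  u <- matrix(runif(grid$height * grid$width), grid$height, grid$width)
  burns <- occ & (u < bp[pmax(grid$species, 1L)])
  grid$species[burns] <- 0L
  grid$growth[burns] <- 0
  grid$age[burns] <- 0L
  grid$fire_flag[burns] <- 1L
  grid$pioneer[burns] <- 1L   # burned ground recolonises as bare soil
  list(grid = grid, burned = sum(burns))
}

#' Apply seasonal grazing offtake
#'
#' Spatially averaged grazing: the seasonal forage demand is
#' `stocking_rate x domain area (ha) x per-LSU seasonal intake` (in growth
#' units). Demand is removed from standing vegetation in order of
#' palatability - grasses first, then shrubs - as a uniform proportional
#' offtake across all cells of the species being grazed; trees are not
#' browsed. Each grazed plant's grazing-stress component is set to its
#' fractional offtake.
#'
#' @param grid an `ecodune_grid`.
#' @param stocking_rate LSU ha^-1.
#' @param config model configuration (`grazing$intake_gu_per_lsu_season`).
#' @return the updated grid.
#' @export
apply_grazing <- function(grid, stocking_rate, config = default_config()) {
  stopifnot(stocking_rate >= 0)
  if (stocking_rate == 0) return(grid)
  area_ha <- grid$width * grid$height * grid$cell_size^2 / 1e4
  demand <- stocking_rate * area_ha * config$grazing$intake_gu_per_lsu_season
  pal <- spp_par(config, "palatability")
  for (sp in order(pal, decreasing = TRUE)) {
    if (pal[sp] <= 0 || demand <= 0) next
    cells <- grid$species == sp
    pool <- sum(grid$growth[cells])
    if (pool <= 0) next
    take <- min(demand, pool)
    frac <- take / pool
    grid$graze_stress[cells] <- pmin(grid$graze_stress[cells] + frac, 1)
    grid$growth[cells] <- grid$growth[cells] * (1 - frac)
    demand <- demand - take
  }
  grid
}
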