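#' Wake recovery length
#'
#' Downwind distance over which wind velocity recovers behind a roughness
#' element: `L = c * height * (1 - porosity)` metres. Taller elements cast
#' longer wakes; porous elements (shrubs) shelter less than bluff elements
#' (grass tussocks) of the same height.
#'
#' @param element_height element height (m), vectorised.
#' @param element_porosity optical porosity in \[0, 1\], vectorised.
#' @param config model configuration (`wind$recovery_coef`).
#' @return recovery length(s) in metres.
#' @export
#' @examples
#' wake_recovery_length(1, 0.2)   # bluff element
#' wake_recovery_length(1, 0.6)   # porous element: shorter wake
wake_recovery_length <- function(element_height, element_porosity,
                                 config = default_config()) {
  stopifnot(all(element_height >= 0),
            all(element_porosity >= 0 & element_porosity <= 1))
  config$wind$recovery_coef * element_height * (1 - element_porosity)
}

#' Wake recovery profile
#'
#' Fraction of the incident wind speed at a given downwind distance
#' (expressed as a fraction of the recovery length) behind a vegetation
#' element. Grass and shrub wakes recover exponentially,
#' `1 - (1 - r0) exp(-k x)`; tree wakes recover logistically (a slow
#' initial rise, matching the elevated-canopy flow regime). Both start at
#' the residual factor `residual` immediately behind the element and reach
#' at least 0.99 at the recovery length.
#'
#' @param species species name or code.
#' @param distance_fraction downwind distance / recovery length, >= 0
#'   (vectorised).
#' @param residual velocity fraction immediately behind the element
#'   (defaults to 0; in the field model it equals the element porosity).
#' @param config model configuration.
#' @return recovery factor(s) in \[0, 1\].
#' @export
wake_profile <- function(species, distance_fraction, residual = 0,
                         config = default_config()) {
  sp <- species_code(species)
  stopifnot(length(sp) == 1, sp %in% 1:3, all(distance_fraction >= 0),
            residual >= 0, residual <= 1)
  x <- pmin(distance_fraction, 1)
  f <- if (sp == 3L) {
    m <- config$wind$tree_mid; r <- config$wind$tree_rate
    lo <- plogis(-r * m); hi <- plogis(r * (1 - m))
    (plogis(r * (x - m)) - lo) / (hi - lo)
  } else {
    k <- config$wind$decay_rate
    (1 - exp(-k * x)) / (1 - exp(-k))
  }
  out <- residual + (1 - residual) * f
  out[distance_fraction >= 1] <- pmax(out[distance_fraction >= 1], 1)
  pmin(out, 1)
}

#' Per-cell wind velocity field for one event
#'
#' Applies the wake-corridor model to an incident wind event: every
#' occupied cell casts a rectangular corridor one footprint wide and one
#' recovery length long, aligned with the (16-bin snapped) wind direction;
#' the velocity factor along the corridor follows the species' wake
#' profile, overlapping wakes combine by taking the minimum factor, and a
#' topographic compression factor `min(cap, 1 + alpha * max(0, upwind
#' slope))` is applied on upwind-facing slopes. On a flat bare grid the
#' field equals the incident speed everywhere.
#'
#' @param grid an `ecodune_grid`.
#' @param event a [sample_wind_event()] result, or a list with `speed`
#'   (m s^-1) and `direction` (degrees from north, direction of origin).
#' @param config model configuration.
#' @return numeric matrix of per-cell wind speeds (m s^-1).
#' @export
compute_velocity_field <- function(grid, event, config = default_config()) {
  stopifnot(event$speed >= 0)
  dirbin <- as.integer(round(event$direction / 22.5)) %% 16L
  h <- pathway_height(grid$species, grid$growth, config)
  por <- pathway_porosity(grid$species, grid$growth, config)
  cpp_velocity_field(
    surface_height(grid), grid$species, h, por,
    event$speed, dirbin, grid$cell_size,
    config$wind$recovery_coef, config$wind$decay_rate,
    config$wind$tree_mid, config$wind$tree_rate,
    config$wind$alpha, config$wind$compression_cap,
    identical(grid$boundary, "periodic")
  )
}
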