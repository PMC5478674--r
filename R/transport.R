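#' Erosion volume from wind velocity
#'
#' Potential sediment release from one cell during one event, from the
#' semi-empirical cubic-type flux law `q(u) = A (u - u_t) u^2` above the
#' entrainment threshold `u_t` (5.1 m s^-1 by default) and zero at or below
#' it. The flux constant `A` is expressed directly in slabs per event, so
#' the returned value is the (continuous) expected slab count, capped by
#' the sand available in the cell; the transport iteration discretises it
#' by stochastic rounding.
#'
#' @param u wind velocity at the cell (m s^-1), vectorised.
#' @param sand_available slabs present in the cell (cap), vectorised or
#'   scalar; default `Inf` gives the uncapped flux.
#' @param config model configuration (`transport$u_threshold`,
#'   `transport$flux_coef`).
#' @return expected slab count(s), >= 0.
#' @export
#' @examples
#' erosion_volume(5.0)   # below threshold: 0
#' erosion_volume(5.1)   # at threshold: still 0
#' erosion_volume(10)    # default calibration: 1 slab
erosion_volume <- function(u, sand_available = Inf,
                           config = default_config()) {
  stopifnot(all(u >= 0))
  ut <- config$transport$u_threshold
  q <- ifelse(u > ut, config$transport$flux_coef * (u - ut) * u^2, 0)
  pmin(q, sand_available)
}

#' Shadow-zone mask for one wind direction
#'
#' Flags every cell lying in the lee of upwind topography, below the line
#' descending at the shadow angle (15 degrees by default) from any upwind
#' crest of the total surface (base + sand). Within shadow zones erosion is
#' suppressed entirely and deposition is complete.
#'
#' @param grid an `ecodune_grid`.
#' @param direction wind direction in degrees from north (snapped to 16
#'   compass bins).
#' @param config model configuration.
#' @return logical matrix, `TRUE` where shadowed.
#' @export
shadow_mask <- function(grid, direction, config = default_config()) {
  dirbin <- as.integer(round(direction / 22.5)) %% 16L
  m <- cpp_shadow_mask(
    surface_height(grid), dirbin, grid$cell_size,
    tan(config$transport$shadow_angle_deg * pi / 180),
    identical(grid$boundary, "periodic")
  )
  m > 0L
}

#' One slab-transport iteration (one wind event)
#'
#' Werner-style transport driven by the event's velocity field. Cells are
#' polled exactly once in random order; a polled cell that is not shadowed,
#' exceeds the entrainment threshold and passes its erosion-probability
#' draw releases its flux-law slab count (stochastically rounded, capped by
#' available sand). Released slabs hop downwind one cell at a time,
#' depositing at each visited cell with the deposition probability
#' (elevated on vegetated cells, certain in shadow zones) until exhausted.
#' Under periodic boundaries every eroded slab is re-deposited, so total
#' sand is conserved exactly; under open boundaries slabs may leave the
#' domain and are tallied as lost.
#'
#' @param grid an `ecodune_grid`.
#' @param velocity_field matrix from [compute_velocity_field()].
#' @param shadow logical matrix from [shadow_mask()]; recomputed here if
#'   omitted (requires `direction`).
#' @param direction wind direction (degrees), used for the hop bearing and
#'   for the shadow mask when `shadow` is missing.
#' @param config model configuration.
#' @return list with the updated `grid` and a `tally` (class
#'   `transport_tally`): eroded/deposited/lost slab counts and transported
#'   volume (m^3) and mass (kg).
#' @export
transport_iteration <- function(grid, velocity_field, direction,
                                shadow = NULL,
                                config = default_config()) {
  if (is.null(shadow)) shadow <- shadow_mask(grid, direction, config)
  dirbin <- as.integer(round(direction / 22.5)) %% 16L
  tp <- config$transport
  order <- sample.int(grid$width * grid$height) - 1L  # polled once, random
  res <- cpp_transport_iteration(
    grid$sand, grid$base, grid$species, velocity_field,
    shadow + 0L, order, dirbin, grid$cell_size, grid$slab_height,
    tp$u_threshold, tp$flux_coef, tp$p_e_bare, tp$p_e_veg,
    tp$p_d_bare, tp$p_d_veg,
    identical(grid$boundary, "periodic")
  )
  grid$sand <- res$sand
  cell_area <- grid$cell_size^2
  vol <- res$eroded * cell_area * grid$slab_height
  tally <- structure(list(
    eroded = res$eroded, deposited = res$deposited, lost = res$lost,
    volume_m3 = vol,
    mass_kg = vol * config$grid$bulk_density
  ), class = "transport_tally")
  list(grid = grid, tally = tally)
}

#' Avalanche relaxation to the angle of repose
#'
#' Moves sand slabs down the steepest 8-neighbour descent until no
#' inter-cell slope of the total surface exceeds the local critical angle
#' of repose: 30 degrees for bare sand cells, 40 degrees where the source
#' cell is vegetated. Ties among equally steep descents break at random.
#' Total sand is conserved. A sweep guard aborts with an error if the
#' relaxation fails to converge (which indicates inconsistent slab
#' geometry).
#'
#' @param grid an `ecodune_grid`.
#' @param config model configuration (`transport$repose_*_deg`,
#'   `transport$max_sweeps`).
#' @return the relaxed grid.
#' @export
avalanche_relax <- function(grid, config = default_config()) {
  tp <- config$transport
  res <- cpp_avalanche(
    grid$sand, grid$base, (grid$species > 0L) + 0L,
    grid$cell_size, grid$slab_height,
    tan(tp$repose_bare_deg * pi / 180), tan(tp$repose_veg_deg * pi / 180),
    identical(grid$boundary, "periodic"), as.integer(tp$max_sweeps)
  )
  if (res$converged == 0L)
    stop("avalanche relaxation did not converge within ",
         tp$max_sweeps, " sweeps; check slab geometry", call. = FALSE)
  grid$sand <- res$sand
  grid
}
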