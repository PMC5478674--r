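#' Initialise a simulation grid
#'
#' Creates the lattice world state: per-cell sand depth (in slabs), an
#' immobile base surface, and the vegetation layer (species, growth units,
#' age). A fraction `cover_fraction` of cells is occupied by plants drawn
#' from `species_mix`; occupied cells start partway along their species'
#' growth pathway so the initial community is not a monoculture of
#' seedlings. Sand depth is uniform-random within `sand_seed_range`.
#'
#' @param width,height grid dimensions in cells (columns, rows).
#' @param cover_fraction fraction of cells initially occupied, in \[0, 1\].
#' @param species_mix named numeric vector of proportions over
#'   `c("grass","shrub","tree")`; must sum to 1. Missing names count as 0.
#' @param sand_seed_range integer length-2 vector, inclusive uniform range of
#'   initial sand depth in slabs. Defaults to the configured range.
#' @param config an [default_config()] list.
#' @param start_year,start_season initial model clock.
#' @return An object of class `ecodune_grid`: a list of matrices (`sand`,
#'   `base`, `species`, `growth`, `age`, ...) plus geometry and clock.
#' @export
#' @examples
#' set.seed(1)
#' g <- init_grid(20, 20, 0.5, c(grass = 1))
#' sum(g$species > 0)  # 200 occupied cells
init_grid <- function(width, height, cover_fraction,
                      species_mix = c(grass = 0.5, shrub = 0.35, tree = 0.15),
                      sand_seed_range = NULL,
                      config = default_config(),
                      start_year = 1L, start_season = "DJF") {
  if (length(width) != 1 || length(height) != 1 ||
      !is.finite(width) || !is.finite(height) || width < 1 || height < 1)
    stop("grid dimensions 'width'/'height' must be positive integers",
         call. = FALSE)
  width <- as.integer(width); height <- as.integer(height)
  if (!is.finite(cover_fraction) || cover_fraction < 0 || cover_fraction > 1)
    stop("'cover_fraction' must lie in [0, 1]", call. = FALSE)
  mix <- setNames(numeric(3), SPECIES_NAMES)
  if (length(species_mix)) {
    if (is.null(names(species_mix)) ||
        !all(names(species_mix) %in% SPECIES_NAMES))
      stop("'species_mix' must be named with grass/shrub/tree", call. = FALSE)
    mix[names(species_mix)] <- species_mix
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("'species_mix' proportions must be non-negative and sum to 1",
         call. = FALSE)
  if (is.null(sand_seed_range)) sand_seed_range <- config$grid$sand_seed_range
  if (length(sand_seed_range) != 2 || any(sand_seed_range < 0) ||
      sand_seed_range[1] > sand_seed_range[2])
    stop("'sand_seed_range' must be a non-negative increasing pair",
         call. = FALSE)

  n <- width * height
  sand <- matrix(
    sample.int(sand_seed_range[2] - sand_seed_range[1] + 1L, n,
               replace = TRUE) + as.integer(sand_seed_range[1]) - 1L,
    nrow = height, ncol = width
  )
  species <- matrix(0L, height, width)
  growth <- matrix(0, height, width)
  age <- matrix(0L, height, width)

  n_occ <- round(cover_fraction * n)
  if (n_occ > 0) {
    cells <- sample.int(n, n_occ)
    sp <- sample.int(3L, n_occ, replace = TRUE, prob = mix)
    species[cells] <- sp
    gmax <- spp_par(config, "g_max")
    # start between 20% and 80% of the pathway; age ~ one good season/unit
    growth[cells] <- runif(n_occ, 0.2, 0.8) * gmax[sp]
    age[cells] <- as.integer(round(growth[cells]))
  }

  structure(list(
    width = width, height = height,
    cell_size = config$grid$cell_size,
    slab_height = config$grid$slab_height,
    boundary = config$grid$boundary,
    sand = sand,
    base = matrix(0, height, width),
    species = species,
    growth = growth,
    age = age,
    fire_flag = matrix(0L, height, width),
    pioneer = matrix(0L, height, width),
    graze_stress = matrix(0, height, width),
    sand_ref = sand,   # season-start sand, for the sediment-balance stress
    clock = list(year = as.integer(start_year),
                 season = match.arg(start_season, SEASONS),
                 event = 0L)
  ), class = "ecodune_grid")
}

#' @export
print.ecodune_grid <- function(x, ...) {
  n <- x$width * x$height
  occ <- sum(x$species > 0)
  cat(sprintf(
    "<ecodune_grid> %d x %d cells (%.0f m), %s boundaries\n",
    x$width, x$height, x$cell_size * max(x$width, x$height), x$boundary))
  cat(sprintf("  clock: year %d, %s, event %d\n",
              x$clock$year, x$clock$season, x$clock$event))
  cat(sprintf("  cover: %.1f%% (%d grass, %d shrub, %d tree)\n",
              100 * occ / n, sum(x$species == 1L), sum(x$species == 2L),
              sum(x$species == 3L)))
  cat(sprintf("  sand: %d slabs total, mean depth %.1f slabs\n",
              sum(x$sand), mean(x$sand)))
  invisible(x)
}

#' Total surface height
#'
#' Base substrate plus sand, in metres.
#'
#' @param grid an `ecodune_grid`.
#' @return numeric matrix of surface heights (m).
#' @export
surface_height <- function(grid) {
  grid$base + grid$sand * grid$slab_height
}

#' Concentric neighbourhood shells
#'
#' The extended-Moore neighbourhood of a focal cell: five ordered rings of
#' cell coordinates at Chebyshev distances 1 to 5. Under periodic boundaries
#' coordinates wrap; under open boundaries rings are truncated at the domain
#' edge (this is flagged in the result, not an error).
#'
#' @param grid an `ecodune_grid`.
#' @param cell integer `c(row, col)` of the focal cell.
#' @param n_shells number of rings (default 5).
#' @return A list of class `ecodune_shells` with one two-column matrix
#'   (`row`, `col`) per ring, and attribute `truncated`.
#' @export
shells <- function(grid, cell, n_shells = 5L) {
  if (length(cell) != 2 || any(cell < 1) ||
      cell[1] > grid$height || cell[2] > grid$width)
    stop("'cell' must be c(row, col) inside the grid", call. = FALSE)
  periodic <- identical(grid$boundary, "periodic")
  truncated <- FALSE
  rings <- vector("list", n_shells)
  for (k in seq_len(n_shells)) {
    d <- -k:k
    offs <- rbind(
      cbind(-k, d), cbind(k, d),                 # top and bottom edges
      cbind(d[-c(1, length(d))], -k),            # left edge (no corners)
      cbind(d[-c(1, length(d))], k)              # right edge (no corners)
    )
    r <- cell[1] + offs[, 1]
    c <- cell[2] + offs[, 2]
    if (periodic) {
      r <- ((r - 1) %% grid$height) + 1L
      c <- ((c - 1) %% grid$width) + 1L
    } else {
      keep <- r >= 1 & r <= grid$height & c >= 1 & c <= grid$width
      if (!all(keep)) truncated <- TRUE
      r <- r[keep]; c <- c[keep]
    }
    # on domains narrower than 2k+1 cells, periodic wrapping can map two
    # offsets onto one lattice site; each site belongs to the ring once
    rings[[k]] <- unique(cbind(row = as.integer(r), col = as.integer(c)))
  }
  structure(rings, truncated = truncated, class = "ecodune_shells")
}

#' Plant state at a cell
#'
#' Extracts one cell's occupant as a `plant_state` object with its derived
#' biomass, height and porosity, or `NULL` for a bare cell.
#'
#' @param grid an `ecodune_grid`.
#' @param cell integer `c(row, col)`.
#' @param config model configuration.
#' @return A list of class `plant_state` (`species`, `growth_units`, `age`,
#'   `biomass`, `height`, `porosity`) or `NULL`.
#' @export
plant_state <- function(grid, cell, config = default_config()) {
  sp <- grid$species[cell[1], cell[2]]
  if (sp == 0L) return(NULL)
  g <- grid$growth[cell[1], cell[2]]
  structure(list(
    species = SPECIES_NAMES[sp],
    growth_units = g,
    age = grid$age[cell[1], cell[2]],
    biomass = pathway_biomass(sp, g, config),
    height = pathway_height(sp, g, config),
    porosity = pathway_porosity(sp, g, config)
  ), class = "plant_state")
}

#' Maximum inter-cell surface slope
#'
#' Steepest slope angle between any pair of 8-neighbour cells, computed on
#' the total surface (base + sand). Diagonal neighbours use the diagonal
#' cell-centre distance.
#'
#' @param grid an `ecodune_grid`.
#' @return maximum slope angle in degrees.
#' @export
max_slope_deg <- function(grid) {
  cpp_max_slope(surface_height(grid), grid$cell_size,
                identical(grid$boundary, "periodic")) * 180 / pi
}

# advance the model clock by one season
advance_season <- function(clock) {
  i <- match(clock$season, SEASONS)
  if (i == 4L) {
    clock$year <- clock$year + 1L
    clock$season <- SEASONS[1]
  } else {
    clock$season <- SEASONS[i + 1L]
  }
  clock$event <- 0L
  clock
}
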