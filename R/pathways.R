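#' Growth-pathway mappings
#'
#' Each species follows a bounded nonlinear growth pathway parameterised in
#' abstract growth units `g` on `[0, g_max]`. Biomass follows a normalised
#' logistic in `g` (slow start, fast middle, saturating), height a concave
#' power law, and porosity a gentle linear increase with size. All three are
#' monotone non-decreasing in `g`. Shrubs are more porous than grasses at
#' equal height (porous canopies versus bluff grass tussocks), which drives
#' their weaker sheltering of the sand surface.
#'
#' These are vectorised over cells: `species` is an integer code matrix or
#' vector (1 grass, 2 shrub, 3 tree; 0 bare gives 0/NA output) and `growth`
#' the matching growth units.
#'
#' @param species integer species codes (0-3), any shape.
#' @param growth growth units, same shape.
#' @param config model configuration.
#' @return numeric of the same shape: biomass (arbitrary units), height (m)
#'   or porosity (0-1; 0 for bare cells).
#' @name growth-pathway
NULL

# normalised logistic on [0,1] with f(0)=0, f(1)=1
logistic01 <- function(x, rate = 6) {
  lo <- plogis(-rate / 2)
  hi <- plogis(rate / 2)
  (plogis(rate * (x - 0.5)) - lo) / (hi - lo)
}

#' @rdname growth-pathway
#' @export
pathway_biomass <- function(species, growth, config = default_config()) {
  gmax <- spp_par(config, "g_max")
  bmax <- spp_par(config, "b_max")
  out <- numeric(length(species))
  occ <- species > 0
  x <- pmin(pmax(growth[occ] / gmax[species[occ]], 0), 1)
  out[occ] <- bmax[species[occ]] * logistic01(x)
  dim(out) <- dim(species)
  out
}

#' @rdname growth-pathway
#' @export
pathway_height <- function(species, growth, config = default_config()) {
  gmax <- spp_par(config, "g_max")
  hmax <- spp_par(config, "h_max")
  hexp <- spp_par(config, "h_exp")
  out <- numeric(length(species))
  occ <- species > 0
  x <- pmin(pmax(growth[occ] / gmax[species[occ]], 0), 1)
  out[occ] <- hmax[species[occ]] * x^hexp[species[occ]]
  dim(out) <- dim(species)
  out
}

#' @rdname growth-pathway
#' @export
pathway_porosity <- function(species, growth, config = default_config()) {
  gmax <- spp_par(config, "g_max")
  pmin_ <- spp_par(config, "por_min")
  pmax_ <- spp_par(config, "por_max")
  out <- numeric(length(species))
  occ <- species > 0
  x <- pmin(pmax(growth[occ] / gmax[species[occ]], 0), 1)
  out[occ] <- pmin_[species[occ]] +
    (pmax_[species[occ]] - pmin_[species[occ]]) * x
  dim(out) <- dim(species)
  out
}
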