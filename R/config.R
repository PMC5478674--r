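#' Default model configuration
#'
#' Returns the reference parameterisation of the simulator as a nested list.
#' Every tunable quantity of the model lives here: species growth pathways
#' and stress responses, the neighbourhood interaction kernel, recruitment
#' priors, wake/wind parameters, slab-transport parameters and disturbance
#' constants. Values not fixed by field measurements are declared defaults
#' chosen to give qualitatively realistic Kalahari-type savanna behaviour;
#' see the package vignette for the rationale behind each block.
#'
#' Units: lengths in metres, precipitation in mm per season, wind speed in
#' m s^-1, sand in slabs of `grid$slab_height` metres, angles in degrees.
#'
#' @param ... named overrides merged recursively into the defaults, e.g.
#'   `default_config(wind = list(recovery_coef = 10))`.
#' @return A nested list of class `ecodune_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$transport$u_threshold
default_config <- function(...) {
  cfg <- list(
    grid = list(
      cell_size = 1,          # m per cell edge; plant footprint ~ one cell
      slab_height = 0.1,      # m of sand per slab (Werner convention)
      boundary = "periodic",
      sand_seed_range = c(5L, 15L),  # initial random sand depth, slabs
      bulk_density = 2000     # kg m^-3
    ),
    clock = list(events_per_season = 20L),
    species = list(
      grass = list(
        code = 1L, g_max = 10, lifespan_seasons = 20L,
        b_max = 1, h_max = 0.5, h_exp = 0.7,
        por_min = 0.16, por_max = 0.20,
        precip_harsh = 25, precip_opt = 110,
        sed_tol_slabs = 2, burn_prob = 0.95, palatability = 1.0
      ),
      shrub = list(
        code = 2L, g_max = 30, lifespan_seasons = 160L,
        b_max = 5, h_max = 1.5, h_exp = 0.7,
        por_min = 0.45, por_max = 0.55,
        precip_harsh = 10, precip_opt = 60,
        sed_tol_slabs = 5, burn_prob = 0.60, palatability = 0.3
      ),
      tree = list(
        code = 3L, g_max = 60, lifespan_seasons = 400L,
        b_max = 20, h_max = 6.0, h_exp = 0.7,
        por_min = 0.35, por_max = 0.45,
        precip_harsh = 40, precip_opt = 120,
        sed_tol_slabs = 8, burn_prob = 0.25, palatability = 0.0
      )
    ),
    # signed shell weights: facilitation (+) close in, competition (-) far out
    kernel = list(
      shell_weights = c(0.4, 0.2, -0.3, -0.4, -0.5),
      squash_rate = 4,
      # sensitivity to neighbourhood interaction declines with own biomass:
      # sens = 1 - sens_slope * biomass / b_max(tree)
      sens_slope = 0.8
    ),
    stress = list(
      # order: neighbourhood, precipitation, biomass, age, sediment,
      # grazing, fire
      weights = rep(1 / 7, 7),
      p0 = 0.01,        # background seasonal mortality floor
      squash_rate = 8   # steepness of stress -> mortality logistic
    ),
    recruitment = list(
      r_base = 0,           # moisture-independent recruitment
      r_moisture = 0.5,     # weight of seasonal moisture suitability
      r_facilitation = 0.3, # weight of shell 1-2 facilitation
      bare_prior = c(grass = 0.7, shrub = 0.2, tree = 0.1),
      copy_blend = 0.2,     # weight of the prior when neighbours exist
      suit_floor = 0.05     # minimum species weight multiplier
    ),
    wind = list(
      recovery_coef = 7,    # heights-to-recover scale c in L = c h (1 - phi)
      decay_rate = 5,       # k of the exponential grass/shrub wake profile
      tree_mid = 0.5,       # midpoint of the logistic tree wake profile
      tree_rate = 12,       # steepness of the logistic tree wake profile
      alpha = 0.5,          # topographic compression coefficient
      compression_cap = 1.5
    ),
    transport = list(
      u_threshold = 5.1,             # entrainment threshold, m s^-1
      flux_coef = 1 / ((10 - 5.1) * 100),  # slabs per (u-ut) u^2; 1 slab at u=10
      p_e_bare = 1.0, p_e_veg = 0.2, # erosion probabilities
      p_d_bare = 0.6, p_d_veg = 1.0, # deposition probabilities
      shadow_angle_deg = 15,
      repose_bare_deg = 30, repose_veg_deg = 40,
      max_sweeps = 1000000L
    ),
    grazing = list(intake_gu_per_lsu_season = 20000),
    fire = list(season = "SON")
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("configuration overrides must be named", call. = FALSE)
    cfg <- modifyList(cfg, dots)
  }
  structure(cfg, class = "ecodune_config")
}

#' Load a configuration from a YAML file
#'
#' Reads a YAML file whose top-level keys mirror [default_config()] and
#' merges it over the defaults, so a file need only state the values it
#' changes.
#'
#' @param path path to a YAML file.
#' @return An `ecodune_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  overrides <- yaml::read_yaml(path)
  cfg <- default_config()
  structure(modifyList(cfg, overrides), class = "ecodune_config")
}

# species-indexed parameter vector, e.g. spp_par(cfg, "g_max") -> c(10,30,60)
spp_par <- function(config, field) {
  vapply(config$species, function(s) as.numeric(s[[field]]), numeric(1))
}

check_weights <- function(weights, n, what = "weights") {
  if (length(weights) != n || any(!is.finite(weights)) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop(what, " must be ", n, " non-negative values summing to 1",
         call. = FALSE)
  invisible(weights)
}
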