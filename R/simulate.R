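# deterministic sub-stream seed for (seed, year, season, stage); all
# arithmetic stays exact in doubles and the result fits a 32-bit integer
stream_seed <- function(seed, year, season_idx, stage) {
  as.integer((seed * 2654435 + year * 9973 + season_idx * 2281 +
                stage * 7919) %% 2147483587)
}

#' Run the coupled simulation over a climate series
#'
#' The main driver: iterates season by season over a [climate_series()].
#' Each season consists of `clock$events_per_season` wind events (sample an
#' event from the wind climatology, compute the wake-corridor velocity
#' field and shadow mask, run one slab-transport iteration, relax
#' avalanches), then the disturbance sub-modules (grazing offtake; a fire
#' event if one is due) and the synchronous vegetation update, after which
#' one record of landscape statistics is taken from the end-of-season grid
#' state.
#'
#' All randomness is drawn from per-(year, season, stage) sub-streams
#' derived from `seed`, so a run is bit-reproducible.
#'
#' @param grid initial `ecodune_grid` state.
#' @param series a [climate_series()] covering the years to simulate.
#' @param wind a [wind_climatology()].
#' @param config model configuration.
#' @param regime optional [disturbance_regime()].
#' @param seed integer seed for the run.
#' @param fire_start_year origin of the fire-return clock; defaults to the
#'   first year of the series.
#' @return A data frame of class `run_result`, one row per season:
#'   `year`, `season`, `density`, `grass_cover`, `shrub_cover`,
#'   `tree_cover`, `grass_shrub_ratio`, `transport_m3`, `transport_kg`,
#'   `eroded_slabs`, `burned_cells`, with the final grid in attribute
#'   `final_grid`.
#' @export
run_simulation <- function(grid, series, wind = default_wind_climatology(),
                           config = default_config(), regime = NULL,
                           seed = 1L, fire_start_year = NULL) {
  stopifnot(inherits(series, "climate_series"))
  if (is.null(fire_start_year)) fire_start_year <- min(series$year)
  n_events <- config$clock$events_per_season
  yrs <- sort(unique(series$year))
  grid$clock$year <- yrs[1]
  grid$clock$season <- SEASONS[1]
  precip <- series$precip_mm
  names(precip) <- paste(series$year, series$season)

  n_rec <- length(yrs) * 4L
  rec <- list(
    year = integer(n_rec), season = character(n_rec),
    density = numeric(n_rec), grass_cover = numeric(n_rec),
    shrub_cover = numeric(n_rec), tree_cover = numeric(n_rec),
    grass_shrub_ratio = numeric(n_rec), transport_m3 = numeric(n_rec),
    transport_kg = numeric(n_rec), eroded_slabs = numeric(n_rec),
    burned_cells = integer(n_rec)
  )
  r <- 0L
  for (yr in yrs) {
    for (si in 1:4) {
      season <- SEASONS[si]
      p_season <- precip[[paste(yr, season)]]

      set.seed(stream_seed(seed, yr, si, 1L))  # wind & transport stream
      eroded <- 0; vol <- 0; mass <- 0
      for (ev in seq_len(n_events)) {
        event <- sample_wind_event(wind, season)
        if (event$speed > config$transport$u_threshold) {
          vf <- compute_velocity_field(grid, event, config)
          sh <- shadow_mask(grid, event$direction, config)
          tr <- transport_iteration(grid, vf, event$direction, sh, config)
          grid <- tr$grid
          if (tr$tally$eroded > 0) grid <- avalanche_relax(grid, config)
          eroded <- eroded + tr$tally$eroded
          vol <- vol + tr$tally$volume_m3
          mass <- mass + tr$tally$mass_kg
        }
        grid$clock$event <- ev
      }

      set.seed(stream_seed(seed, yr, si, 2L))  # disturbance stream
      burned <- 0L
      if (!is.null(regime)) {
        if (regime$stocking_rate > 0)
          grid <- apply_grazing(grid, regime$stocking_rate, config)
        if (fire_due(list(year = yr, season = season), regime,
                     fire_start_year, config)) {
          fr <- apply_fire(grid, config)
          grid <- fr$grid
          burned <- fr$burned
        }
      }

      set.seed(stream_seed(seed, yr, si, 3L))  # vegetation stream
      grid <- vegetation_step(grid, p_season, config)

      st <- landscape_stats(grid)
      r <- r + 1L
      rec$year[r] <- yr; rec$season[r] <- season
      rec$density[r] <- st$density
      rec$grass_cover[r] <- st$grass_cover
      rec$shrub_cover[r] <- st$shrub_cover
      rec$tree_cover[r] <- st$tree_cover
      rec$grass_shrub_ratio[r] <- st$grass_shrub_ratio
      rec$transport_m3[r] <- vol
      rec$transport_kg[r] <- mass
      rec$eroded_slabs[r] <- eroded
      rec$burned_cells[r] <- burned
      grid$clock <- advance_season(grid$clock)
    }
  }
  out <- as.data.frame(rec, stringsAsFactors = FALSE)
  attr(out, "final_grid") <- grid
  attr(out, "seed") <- seed
  class(out) <- c("run_result", "data.frame")
  out
}

#' Equilibrium experiment
#'
#' Runs the model to equilibrium under stationary seasonal forcing
#' (per-season means, e.g. from [equilibrium_year_forcing()]) with low or
#' high interannual variability, and summarises the landscape over the
#' last `last_years` years separated into wet (DJF) and dry (JJA) season,
#' reporting means and coefficients of variation.
#'
#' @param season_means named per-season mean precipitation (mm).
#' @param variability `"low"` (sigma 30 mm annual equivalent), `"high"`
#'   (160 mm) or `"none"`.
#' @param years run length in model years.
#' @param width,height,cover_fraction,species_mix initial grid settings
#'   (the domain starts at `cover_fraction` cover with random sand depth).
#' @param wind,config,seed as in [run_simulation()].
#' @param last_years averaging window at the end of the run.
#' @return list with `series` (the full `run_result`), `summary` (a data
#'   frame of seasonal means and CVs over the last window), and
#'   `final_grid`.
#' @export
run_equilibrium <- function(season_means, variability = "low", years = 200,
                            width = 150, height = 150,
                            cover_fraction = 0.9,
                            species_mix = c(grass = 0.5, shrub = 0.35,
                                            tree = 0.15),
                            wind = default_wind_climatology(),
                            config = default_config(), seed = 1L,
                            last_years = 10) {
  spec <- scenario_spec(seq_len(years), season_means,
                        variability = variability,
                        site = "equilibrium", scenario = variability)
  series <- generate_precip_trajectory(spec, seed = stream_seed(seed, 0, 1, 9L))
  set.seed(stream_seed(seed, 0, 1, 8L))
  grid <- init_grid(width, height, cover_fraction, species_mix,
                    config = config)
  run <- run_simulation(grid, series, wind, config, seed = seed)
  tail_run <- run[run$year > years - last_years, ]
  cv <- function(x) if (mean(x) == 0) 0 else sd(x) / mean(x)
  summ <- do.call(rbind, lapply(c("DJF", "JJA"), function(s) {
    sub <- tail_run[tail_run$season == s, ]
    data.frame(
      season = s,
      density = mean(sub$density), density_cv = cv(sub$density),
      grass_shrub_ratio = mean(sub$grass_shrub_ratio),
      ratio_cv = cv(sub$grass_shrub_ratio),
      tree_cover = mean(sub$tree_cover), tree_cv = cv(sub$tree_cover),
      transport_m3 = mean(sub$transport_m3),
      transport_cv = cv(sub$transport_m3)
    )
  }))
  list(series = run, summary = summ,
       final_grid = attr(run, "final_grid"))
}

#' Transient ensemble experiment
#'
#' Runs an ensemble of transient simulations over a (typically 1960-2100)
#' forcing. When `forcing` is a [scenario_spec()] the precipitation
#' trajectory is re-drawn for every ensemble member (each member sees its
#' own noise realisation around the projected trajectory); a fixed
#' [climate_series()] is used as-is for all members. All members start from
#' the same initial grid (e.g. a stored equilibrium state).
#'
#' @param forcing a `scenario_spec` or `climate_series`.
#' @param n_runs ensemble size.
#' @param init_grid initial `ecodune_grid` shared by all members.
#' @param wind,config,regime,seed as in [run_simulation()].
#' @return list with `runs` (list of `run_result`), `ensemble` (per-season
#'   mean/min/max across members of density, grass:shrub ratio and
#'   transport) and `smoothed` (3-year moving averages of the ensemble
#'   mean).
#' @export
run_transient <- function(forcing, n_runs = 10, init_grid,
                          wind = default_wind_climatology(),
                          config = default_config(), regime = NULL,
                          seed = 1L) {
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    series <- if (inherits(forcing, "scenario_spec"))
      generate_precip_trajectory(forcing,
                                 seed = stream_seed(seed, r, 1, 9L))
    else forcing
    runs[[r]] <- run_simulation(init_grid, series, wind, config,
                                regime = regime,
                                seed = stream_seed(seed, r, 2, 9L))
  }
  key <- paste(runs[[1]]$year, runs[[1]]$season)
  stat_mat <- function(col)
    sapply(runs, function(x) x[[col]])
  ens <- data.frame(year = runs[[1]]$year, season = runs[[1]]$season)
  for (col in c("density", "grass_shrub_ratio", "transport_m3")) {
    m <- stat_mat(col)
    ens[[paste0(col, "_mean")]] <- rowMeans(m)
    ens[[paste0(col, "_min")]] <- apply(m, 1, min)
    ens[[paste0(col, "_max")]] <- apply(m, 1, max)
  }
  smoothed <- ens[c("year", "season")]
  for (col in c("density_mean", "grass_shrub_ratio_mean",
                "transport_m3_mean"))
    smoothed[[col]] <- moving_average_seasonal(ens[[col]], years = 3)
  list(runs = runs, ensemble = ens, smoothed = smoothed)
}

#' Fire-by-grazing factorial experiment
#'
#' Runs the model across a factorial of fire frequencies and grazing
#' pressures, and summarises population density and grass:shrub ratio over
#' windows of years centred on each key year (the 10 years around the
#' date, e.g. 2025-2035 for 2030), as means and standard deviations
#' averaged across ensemble members.
#'
#' @param forcing a `scenario_spec` or `climate_series` (transient
#'   forcing, typically 1960-2100).
#' @param fire_levels,grazing_levels character vectors of regime levels.
#' @param n_runs ensemble members per regime cell.
#' @param key_years years at which the matrices are evaluated.
#' @param init_grid shared initial grid.
#' @param wind,config,seed as in [run_simulation()].
#' @return list with `matrix` (a data frame: one row per fire x grazing x
#'   key year with density and ratio mean/sd) and `runs` (nested list of
#'   `run_result` per regime).
#' @export
run_fire_grazing_matrix <- function(forcing,
                                    fire_levels = c("low", "medium", "high"),
                                    grazing_levels = c("low", "medium",
                                                       "high"),
                                    n_runs = 3, key_years = c(2030, 2060),
                                    init_grid,
                                    wind = default_wind_climatology(),
                                    config = default_config(), seed = 1L) {
  out <- list()
  all_runs <- list()
  cell_i <- 0L
  for (fl in fire_levels) for (gl in grazing_levels) {
    cell_i <- cell_i + 1L
    regime <- disturbance_regime(fire = fl, grazing = gl)
    tr <- run_transient(forcing, n_runs = n_runs, init_grid = init_grid,
                        wind = wind, config = config, regime = regime,
                        seed = stream_seed(seed, cell_i, 3, 9L))
    all_runs[[paste(fl, gl, sep = ":")]] <- tr$runs
    for (ky in key_years) {
      win <- (ky - 5):(ky + 5)
      per_run <- lapply(tr$runs, function(run) {
        sub <- run[run$year %in% win, ]
        c(density = mean(sub$density),
          ratio = mean(sub$grass_shrub_ratio))
      })
      dens <- vapply(per_run, `[[`, numeric(1), "density")
      rat <- vapply(per_run, `[[`, numeric(1), "ratio")
      out[[length(out) + 1L]] <- data.frame(
        fire = fl, grazing = gl, key_year = ky,
        density_mean = mean(dens),
        density_sd = if (length(dens) > 1) sd(dens) else 0,
        ratio_mean = mean(rat),
        ratio_sd = if (length(rat) > 1) sd(rat) else 0
      )
    }
  }
  list(matrix = do.call(rbind, out), runs = all_runs)
}

#' Synthetic site presets
#'
#' Ready-made seasonal precipitation climatologies for three Kalahari-like
#' sites spanning a north-south rainfall gradient: `"maun"` (wettest,
#' northern), `"tshane"` (intermediate) and `"tsabong"` (driest,
#' southern). The numbers are declared synthetic fixtures shaped like the
#' regional gradient (wet-summer DJF regime, dry JJA winters, gently
#' declining trends), not measured station values; replace them with
#' [load_climate_table()] data for site-specific work.
#'
#' @param site one of `"maun"`, `"tshane"`, `"tsabong"`.
#' @return list with `season_means` (mm), `season_trends` (mm yr^-1) and
#'   `annual_mean` (mm).
#' @export
site_preset <- function(site = c("maun", "tshane", "tsabong")) {
  site <- match.arg(site)
  annual <- switch(site, maun = 460, tshane = 365, tsabong = 295)
  split <- c(DJF = 0.45, MAM = 0.25, JJA = 0.05, SON = 0.25)
  trend_annual <- switch(site, maun = -0.8, tshane = -0.5, tsabong = -0.4)
  list(season_means = annual * split,
       season_trends = trend_annual * split,
       annual_mean = annual)
}
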