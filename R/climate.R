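#' Construct a climate series
#'
#' A climate series holds one seasonal precipitation total (mm) per
#' (year, season) over a contiguous year range, with site and scenario
#' labels. All four seasons must be present for every year and totals must
#' be non-negative.
#'
#' @param df data frame with columns `year`, `season`, `precip_mm`.
#' @param site,scenario labels carried as attributes.
#' @return The validated data frame with class `climate_series`.
#' @export
climate_series <- function(df, site = "synthetic", scenario = "synthetic") {
  need <- c("year", "season", "precip_mm")
  if (!all(need %in% names(df)))
    stop("climate series needs columns year, season, precip_mm",
         call. = FALSE)
  df <- df[need]
  df$year <- as.integer(df$year)
  bad <- which(!df$season %in% SEASONS)
  if (length(bad))
    stop("invalid season at row(s) ", paste(bad, collapse = ", "),
         " (expected DJF/MAM/JJA/SON)", call. = FALSE)
  bad <- which(!is.finite(df$precip_mm) | df$precip_mm < 0)
  if (length(bad))
    stop("negative or missing precipitation at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  yrs <- sort(unique(df$year))
  if (!identical(yrs, seq(min(yrs), max(yrs))))
    stop("year range must be contiguous; missing year(s): ",
         paste(setdiff(seq(min(yrs), max(yrs)), yrs), collapse = ", "),
         call. = FALSE)
  tab <- table(factor(df$season, SEASONS), df$year)
  if (any(tab != 1L)) {
    miss <- which(tab != 1L, arr.ind = TRUE)
    stop("every year needs each season exactly once; first problem: ",
         rownames(tab)[miss[1, 1]], " in year ", colnames(tab)[miss[1, 2]],
         call. = FALSE)
  }
  df <- df[order(df$year, match(df$season, SEASONS)), ]
  rownames(df) <- NULL
  structure(df, site = site, scenario = scenario,
            class = c("climate_series", "data.frame"))
}

#' Specify a synthetic precipitation scenario
#'
#' Defines a seasonal precipitation trajectory as per-season baseline means
#' plus linear trends, with one of four interannual-variability modes:
#' `"none"` (deterministic), `"low"` (sigma = 30 mm annual equivalent),
#' `"high"` (sigma = 160 mm annual equivalent) or `"moving"` (a per-season
#' sigma series derived from 5-year moving windows of a reference series,
#' emulating transient projection spread).
#'
#' The annual-equivalent sigma is partitioned to seasons as
#' `sigma_season = sigma_annual / 2`, so that four independent seasonal
#' deviates sum to the stated annual variance.
#'
#' @param years integer vector (contiguous) of calendar years.
#' @param season_means named numeric, mean seasonal totals (mm) in the first
#'   year, names DJF/MAM/JJA/SON.
#' @param season_trends named numeric, linear trends in mm per year
#'   (default 0).
#' @param variability one of `"none"`, `"low"`, `"high"`, `"moving"`.
#' @param sigma_annual annual-equivalent standard deviation (mm); defaults
#'   to 0, 30 or 160 by mode and is ignored for `"moving"`.
#' @param sigma_table for `"moving"`: data frame `year`, `season`, `sigma`
#'   (seasonal mm), e.g. from [moving_sigma()].
#' @param site,scenario labels.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(years, season_means, season_trends = NULL,
                          variability = c("none", "low", "high", "moving"),
                          sigma_annual = NULL, sigma_table = NULL,
                          site = "synthetic", scenario = "synthetic") {
  variability <- match.arg(variability)
  years <- as.integer(years)
  if (length(years) == 0)
    stop("'years' must be a non-empty year range", call. = FALSE)
  if (!identical(years, seq(years[1], years[length(years)])))
    stop("'years' must be a contiguous increasing range", call. = FALSE)
  if (is.null(names(season_means)) || !all(SEASONS %in% names(season_means)))
    stop("'season_means' must be named DJF/MAM/JJA/SON", call. = FALSE)
  if (any(season_means[SEASONS] < 0))
    stop("'season_means' must be non-negative", call. = FALSE)
  if (is.null(season_trends)) season_trends <- setNames(rep(0, 4), SEASONS)
  if (is.null(names(season_trends)) ||
      !all(SEASONS %in% names(season_trends)))
    stop("'season_trends' must be named DJF/MAM/JJA/SON", call. = FALSE)
  if (is.null(sigma_annual))
    sigma_annual <- switch(variability, none = 0, low = 30, high = 160,
                           moving = NA_real_)
  if (variability == "moving") {
    if (is.null(sigma_table) ||
        !all(c("year", "season", "sigma") %in% names(sigma_table)))
      stop("variability 'moving' needs a 'sigma_table' with columns ",
           "year, season, sigma", call. = FALSE)
  }
  structure(list(
    years = years,
    season_means = season_means[SEASONS],
    season_trends = season_trends[SEASONS],
    variability = variability,
    sigma_annual = sigma_annual,
    sigma_table = sigma_table,
    site = site, scenario = scenario
  ), class = "scenario_spec")
}

#' Generate a seasonal precipitation trajectory
#'
#' Draws one realisation of the scenario: for each (year, season) the
#' deterministic trend value `mean + trend * (year - first_year)` plus a
#' normal deviate with the mode's seasonal sigma, truncated below at zero.
#' With `variability = "none"` (or sigma 0) the output equals the trend
#' exactly.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional integer; if given, seeds the draw for
#'   reproducibility (the global RNG state is restored afterwards).
#' @return A [climate_series()].
#' @export
#' @examples
#' sp <- scenario_spec(2017:2100, c(DJF = 200, MAM = 90, JJA = 10, SON = 60),
#'                     c(DJF = -0.5, MAM = 0, JJA = 0, SON = 0))
#' tr <- generate_precip_trajectory(sp)
#' subset(tr, year == 2100 & season == "DJF")$precip_mm  # 158.5
generate_precip_trajectory <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  yrs <- spec$years
  df <- expand.grid(season = SEASONS, year = yrs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[c("year", "season")]
  trend_val <- spec$season_means[df$season] +
    spec$season_trends[df$season] * (df$year - yrs[1])
  sig <- switch(spec$variability,
    none = 0,
    low = spec$sigma_annual / 2,
    high = spec$sigma_annual / 2,
    moving = {
      key <- paste(df$year, df$season)
      tab <- spec$sigma_table
      m <- match(key, paste(tab$year, tab$season))
      if (anyNA(m))
        stop("sigma_table is missing entries for: ",
             paste(utils::head(key[is.na(m)], 4), collapse = "; "),
             call. = FALSE)
      tab$sigma[m]
    })
  noise <- if (all(sig == 0)) 0 else rnorm(nrow(df), 0, sig)
  df$precip_mm <- pmax(0, unname(trend_val) + noise)
  climate_series(df, site = spec$site, scenario = spec$scenario)
}

#' Aggregate-year forcing for equilibrium runs
#'
#' Per-season mean precipitation over the 21-year window centred on
#' `key_year` (the two decades around it), used as stationary forcing for
#' an equilibrium run representing that year.
#'
#' @param series a [climate_series()].
#' @param key_year centre of the window; `key_year` +/- 10 must lie inside
#'   the series range.
#' @return named numeric, mean seasonal totals (mm) for DJF/MAM/JJA/SON.
#' @export
equilibrium_year_forcing <- function(series, key_year) {
  stopifnot(inherits(series, "climate_series"))
  want <- (key_year - 10):(key_year + 10)
  missing_yrs <- setdiff(want, unique(series$year))
  if (length(missing_yrs))
    stop("window ", key_year - 10, "-", key_year + 10,
         " exceeds the series; missing year(s): ",
         paste(missing_yrs, collapse = ", "), call. = FALSE)
  sub <- series[series$year %in% want, ]
  out <- tapply(sub$precip_mm, factor(sub$season, SEASONS), mean)
  setNames(as.numeric(out), SEASONS)
}

#' Moving-window seasonal standard deviation
#'
#' Per-season standard deviation of seasonal totals over a centred
#' `window`-year moving window, with shrinkage at the series edges (the
#' window is truncated, never padded).
#'
#' @param series a [climate_series()].
#' @param window window length in years (odd, default 5).
#' @return data frame `year`, `season`, `sigma` (mm).
#' @export
moving_sigma <- function(series, window = 5L) {
  stopifnot(inherits(series, "climate_series"))
  yrs <- sort(unique(series$year))
  if (length(yrs) < window)
    stop("series spans ", length(yrs), " years; need at least ", window,
         call. = FALSE)
  half <- (window - 1L) %/% 2L
  out <- expand.grid(season = SEASONS, year = yrs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[c("year", "season")]
  out$sigma <- NA_real_
  for (s in SEASONS) {
    v <- series$precip_mm[series$season == s][order(series$year[series$season == s])]
    sig <- vapply(seq_along(yrs), function(i) {
      idx <- max(1L, i - half):min(length(yrs), i + half)
      sd(v[idx])
    }, numeric(1))
    out$sigma[out$season == s] <- sig[match(out$year[out$season == s], yrs)]
  }
  rownames(out) <- NULL
  out
}

#' Read and write climate tables
#'
#' Plain headered CSV with columns `year`, `season`, `precip_mm`. Reading
#' validates the table (non-negative totals, all four seasons per year) and
#' reports the offending data rows on failure.
#'
#' @param path file path.
#' @param site,scenario labels attached on read.
#' @param series a [climate_series()] to write.
#' @return `load_climate_table()` returns a [climate_series()];
#'   `write_climate_table()` returns `path` invisibly.
#' @export
load_climate_table <- function(path, site = "file", scenario = "file") {
  if (!file.exists(path))
    stop("climate table not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  tryCatch(
    climate_series(df, site = site, scenario = scenario),
    error = function(e) stop("malformed climate table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
}

#' @rdname load_climate_table
#' @export
write_climate_table <- function(series, path) {
  stopifnot(inherits(series, "climate_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

# save/restore the global RNG state around internally seeded draws
get_rng_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
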