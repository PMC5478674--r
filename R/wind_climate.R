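#' Seasonal wind climatology
#'
#' Holds per-season Weibull parameters for wind speed and a probability
#' table over 16 compass direction bins (bin centres at 0, 22.5, ...,
#' 337.5 degrees from north, the direction the wind blows *from*).
#'
#' @param seasons named list (DJF/MAM/JJA/SON) of `c(shape =, scale =)`
#'   Weibull parameters (scale in m s^-1).
#' @param direction_probs numeric length 16, probabilities per compass bin;
#'   must sum to 1.
#' @return A list of class `wind_climatology`.
#' @export
wind_climatology <- function(seasons, direction_probs) {
  if (!all(SEASONS %in% names(seasons)))
    stop("'seasons' must have entries for DJF/MAM/JJA/SON", call. = FALSE)
  for (s in SEASONS) {
    p <- seasons[[s]]
    if (!all(c("shape", "scale") %in% names(p)) ||
        p[["shape"]] <= 0 || p[["scale"]] <= 0)
      stop("season ", s, ": Weibull shape and scale must be positive",
           call. = FALSE)
  }
  if (length(direction_probs) != 16)
    stop("'direction_probs' must have 16 compass bins", call. = FALSE)
  if (any(direction_probs < 0) || abs(sum(direction_probs) - 1) > 1e-6)
    stop("'direction_probs' must be non-negative and sum to 1 ",
         "(unnormalised direction table)", call. = FALSE)
  structure(list(seasons = lapply(seasons[SEASONS], unlist),
                 direction_probs = as.numeric(direction_probs)),
            class = "wind_climatology")
}

#' Synthetic default wind climatology
#'
#' A Kalahari-flavoured synthetic climatology: moderately windy springs
#' (SON), calmer autumns (MAM), Weibull shape ~2, and a directional PDF
#' dominated by northerly-to-westerly bins. These are declared synthetic
#' defaults, not measured values; supply a measured climatology via
#' [wind_climatology()] or [load_wind_climatology()] for site-specific work.
#'
#' @return A `wind_climatology`.
#' @export
default_wind_climatology <- function() {
  dirs <- rep(0.02, 16)
  # concentrate mass on N through W bins (indices 1, 14:16 ~ 0, 292.5-337.5)
  dirs[c(1, 2, 14, 15, 16)] <- c(0.18, 0.08, 0.12, 0.18, 0.16)
  dirs <- dirs / sum(dirs)
  wind_climatology(
    seasons = list(
      DJF = c(shape = 2.2, scale = 5.5),
      MAM = c(shape = 2.0, scale = 4.5),
      JJA = c(shape = 2.1, scale = 5.0),
      SON = c(shape = 2.3, scale = 6.5)
    ),
    direction_probs = dirs
  )
}

#' Load a wind climatology from YAML
#'
#' Expected structure: top-level `seasons:` with per-season `shape`/`scale`
#' and `direction_probs:` with 16 values.
#'
#' @param path YAML file path.
#' @return A `wind_climatology`.
#' @export
load_wind_climatology <- function(path) {
  if (!file.exists(path))
    stop("wind climatology file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  wind_climatology(lapply(y$seasons, unlist), unlist(y$direction_probs))
}

#' Sample a wind event
#'
#' Draws one wind episode for a season: speed from the seasonal Weibull
#' distribution and direction from the 16-bin compass probability table
#' (bin-centre degrees from north). Draws consume the global RNG, so
#' `set.seed()` gives reproducible events.
#'
#' @param climatology a [wind_climatology()].
#' @param season one of DJF/MAM/JJA/SON.
#' @return A list of class `wind_event` with `speed` (m s^-1) and
#'   `direction` (degrees).
#' @export
#' @examples
#' set.seed(42)
#' sample_wind_event(default_wind_climatology(), "SON")
sample_wind_event <- function(climatology, season) {
  stopifnot(inherits(climatology, "wind_climatology"))
  season <- match.arg(season, SEASONS)
  p <- climatology$seasons[[season]]
  speed <- rweibull(1, shape = p[["shape"]], scale = p[["scale"]])
  bin <- sample.int(16L, 1L, prob = climatology$direction_probs)
  structure(list(speed = speed, direction = (bin - 1L) * 22.5),
            class = "wind_event")
}
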