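#' Landscape statistics of a grid state
#'
#' Counts by exhaustive scan: population density (occupied cells / total
#' cells), per-species absolute cover, the grass:shrub ratio (reported as
#' `Inf` with `shrub_free = TRUE` when no shrubs are present - never a
#' silent division), tree-cover proportion, and the transported sediment
#' volume/mass of an accompanying tally, if given.
#'
#' @param grid an `ecodune_grid`.
#' @param tally optional `transport_tally` (from [transport_iteration()]
#'   or accumulated by the drivers).
#' @return A list of class `landscape_stats`.
#' @export
#' @examples
#' set.seed(1)
#' g <- init_grid(20, 20, 0.5, c(grass = 0.6, shrub = 0.3, tree = 0.1))
#' landscape_stats(g)$density
landscape_stats <- function(grid, tally = NULL) {
  n <- grid$width * grid$height
  n_grass <- sum(grid$species == 1L)
  n_shrub <- sum(grid$species == 2L)
  n_tree <- sum(grid$species == 3L)
  occ <- n_grass + n_shrub + n_tree
  structure(list(
    density = occ / n,
    n_grass = n_grass, n_shrub = n_shrub, n_tree = n_tree,
    grass_cover = n_grass / n,
    shrub_cover = n_shrub / n,
    tree_cover = n_tree / n,
    grass_shrub_ratio = if (n_shrub == 0) Inf else n_grass / n_shrub,
    shrub_free = n_shrub == 0,
    transport_m3 = if (is.null(tally)) NA_real_ else tally$volume_m3,
    transport_kg = if (is.null(tally)) NA_real_ else tally$mass_kg
  ), class = "landscape_stats")
}

#' Time below a cover threshold
#'
#' Fraction of seasonal records in which a cover series lies strictly below
#' a threshold, together with the full cumulative-frequency curve. Used to
#' summarise how often grass or shrub cover drops below a management
#' threshold (20% by default) over a simulated century.
#'
#' @param cover numeric vector of seasonal absolute cover values in
#'   \[0, 1\].
#' @param threshold cover threshold (default 0.20).
#' @return list with `fraction` (time strictly below threshold) and
#'   `curve`, a data frame (`cover`, `cum_freq`) giving the empirical
#'   cumulative frequency at each observed cover value.
#' @export
threshold_frequency <- function(cover, threshold = 0.20) {
  if (length(cover) == 0)
    stop("empty cover series", call. = FALSE)
  stopifnot(all(is.finite(cover)))
  xs <- sort(unique(cover))
  list(
    fraction = mean(cover < threshold),
    curve = data.frame(cover = xs,
                       cum_freq = vapply(xs, function(x) mean(cover <= x),
                                         numeric(1)))
  )
}

#' Seasonal moving average
#'
#' Centred moving average of a seasonal series over a window of `years`
#' calendar years (4 x years seasonal records), truncated at the series
#' edges. Used for the 3-year smoothing of transient run output.
#'
#' @param x numeric seasonal series.
#' @param years window half-span in years (default 3).
#' @return numeric vector, same length as `x`.
#' @export
moving_average_seasonal <- function(x, years = 3) {
  w <- as.integer(years * 4)
  half <- w %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Normalise run statistics to a baseline
#'
#' Divides the columns of a per-season run record by the corresponding
#' annual baseline values (the mean of the four seasons of a chosen
#' baseline year of a baseline run), so that the baseline year of the
#' baseline run maps to 1 by construction.
#'
#' @param run data frame of per-season statistics (as returned by
#'   [run_simulation()]).
#' @param baseline data frame of the baseline run (may be the same run).
#' @param baseline_year year whose four seasons define the baseline.
#' @param cols columns to normalise.
#' @return `run` with the chosen columns divided by their baseline means.
#' @export
normalise_to_baseline <- function(run, baseline, baseline_year,
                                  cols = c("density", "grass_shrub_ratio",
                                           "tree_cover", "transport_m3")) {
  base_rows <- baseline$year == baseline_year
  if (!any(base_rows))
    stop("baseline year ", baseline_year, " not present in baseline run",
         call. = FALSE)
  for (cl in cols) {
    b <- mean(baseline[[cl]][base_rows])
    run[[cl]] <- if (is.finite(b) && b != 0) run[[cl]] / b else NA_real_
  }
  run
}
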