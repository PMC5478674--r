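test_that("landscape statistics equal a brute-force recount", {
  set.seed(70)
  g <- init_grid(30, 30, 0.6)
  st <- landscape_stats(g)
  # independent scan
  cnt <- c(0, 0, 0)
  for (r in 1:30) for (c in 1:30) {
    sp <- g$species[r, c]
    if (sp > 0) cnt[sp] <- cnt[sp] + 1
  }
  expect_equal(st$density, sum(cnt) / 900)
  expect_equal(st$n_grass, cnt[1])
  expect_equal(st$grass_shrub_ratio, cnt[1] / cnt[2])
  expect_equal(st$tree_cover, cnt[3] / 900)
  expect_lte(st$tree_cover, st$density)

  # fully occupied domain
  g1 <- init_grid(15, 15, 1)
  expect_equal(landscape_stats(g1)$density, 1)

  # constructed 2:1 ratio
  g2 <- init_grid(10, 10, 0)
  g2$species[1:6] <- 1L; g2$species[7:9] <- 2L
  expect_equal(landscape_stats(g2)$grass_shrub_ratio, 2)

  # shrub-free grid: Inf sentinel with a flag, not a silent NaN
  g3 <- init_grid(10, 10, 0.5, c(grass = 1))
  s3 <- landscape_stats(g3)
  expect_true(is.infinite(s3$grass_shrub_ratio))
  expect_true(s3$shrub_free)
})

test_that("threshold frequency counts strictly-below seasons", {
  expect_equal(threshold_frequency(rep(0.5, 40))$fraction, 0)
  expect_equal(threshold_frequency(c(0.1, 0.3, 0.1, 0.3))$fraction, 0.5)
  set.seed(71)
  x <- runif(200)
  tf <- threshold_frequency(x, 0.35)
  expect_equal(tf$fraction, sum(x < 0.35) / 200)  # counting oracle
  # the cumulative curve is a proper ecdf
  expect_true(all(diff(tf$curve$cum_freq) > 0))
  expect_equal(max(tf$curve$cum_freq), 1)
  expect_error(threshold_frequency(numeric(0)), "empty")
})

test_that("seasonal moving average smooths and preserves constants", {
  expect_equal(moving_average_seasonal(rep(3.5, 40)), rep(3.5, 40))
  x <- sin(1:40)
  ma <- moving_average_seasonal(x)
  expect_equal(length(ma), 40)
  expect_lt(sd(ma), sd(x))
})

test_that("normalising a run against its own baseline gives unity", {
  set.seed(72)
  sp <- scenario_spec(2000:2004, c(DJF = 150, MAM = 80, JJA = 15, SON = 70),
                      variability = "low")
  ser <- generate_precip_trajectory(sp, seed = 1)
  g <- init_grid(15, 15, 0.8)
  run <- run_simulation(g, ser, seed = 4)
  norm <- normalise_to_baseline(run, run, baseline_year = 2002,
                                cols = c("density", "tree_cover"))
  expect_equal(mean(norm$density[norm$year == 2002]), 1)
  expect_equal(mean(norm$tree_cover[norm$year == 2002]), 1)
  expect_error(normalise_to_baseline(run, run, 1990), "baseline year")
})

test_that("the simulation driver is seeded and bookkeeps one row per season", {
  sp <- scenario_spec(1:3, c(DJF = 160, MAM = 80, JJA = 15, SON = 70),
                      variability = "low")
  ser <- generate_precip_trajectory(sp, seed = 2)
  set.seed(73); g <- init_grid(15, 15, 0.8)
  a <- run_simulation(g, ser, seed = 11)
  b <- run_simulation(g, ser, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "final_grid"), attr(b, "final_grid"))
  expect_equal(nrow(a), 12)
  expect_equal(a$season, rep(c("DJF", "MAM", "JJA", "SON"), 3))
  c_ <- run_simulation(g, ser, seed = 12)
  expect_false(identical(a$density, c_$density))
})

test_that("equilibrium runs summarise the final window by season", {
  eq <- run_equilibrium(c(DJF = 170, MAM = 85, JJA = 15, SON = 75),
                        variability = "low", years = 12,
                        width = 20, height = 20, seed = 21,
                        last_years = 5)
  expect_equal(nrow(eq$series), 48)
  expect_equal(eq$summary$season, c("DJF", "JJA"))
  expect_true(all(is.finite(eq$summary$density)))
  expect_true(all(eq$summary$density >= 0 & eq$summary$density <= 1))
  # bit-reproducible
  eq2 <- run_equilibrium(c(DJF = 170, MAM = 85, JJA = 15, SON = 75),
                         variability = "low", years = 12,
                         width = 20, height = 20, seed = 21,
                         last_years = 5)
  expect_identical(eq$summary, eq2$summary)
})

test_that("transient ensembles envelope every member", {
  sp <- scenario_spec(1960:1964, c(DJF = 160, MAM = 80, JJA = 15, SON = 70),
                      variability = "low")
  set.seed(74); g <- init_grid(15, 15, 0.8)
  tr <- run_transient(sp, n_runs = 3, init_grid = g, seed = 31)
  expect_length(tr$runs, 3)
  expect_equal(nrow(tr$runs[[1]]), 20)
  # pointwise min/max contain every run
  for (r in tr$runs) {
    expect_true(all(r$density >= tr$ensemble$density_min - 1e-12))
    expect_true(all(r$density <= tr$ensemble$density_max + 1e-12))
  }
  # ensemble members see different forcing realisations
  expect_false(identical(tr$runs[[1]]$density, tr$runs[[2]]$density))
  # moving average of the constant-length series has the same length
  expect_equal(nrow(tr$smoothed), 20)
})

test_that("the fire-grazing matrix aggregates match the stored runs", {
  sp <- scenario_spec(2024:2036, c(DJF = 160, MAM = 80, JJA = 15, SON = 70),
                      variability = "low")
  set.seed(75); g <- init_grid(15, 15, 0.8)
  fm <- run_fire_grazing_matrix(sp, fire_levels = "high",
                                grazing_levels = "low", n_runs = 2,
                                key_years = 2030, init_grid = g, seed = 41)
  expect_equal(nrow(fm$matrix), 1)
  expect_true(is.finite(fm$matrix$density_mean))
  expect_true(is.finite(fm$matrix$density_sd))

  # re-aggregation oracle: the 2030 window is the 11 years 2025-2035
  runs <- fm$runs[["high:low"]]
  per_run <- vapply(runs, function(r)
    mean(r$density[r$year >= 2025 & r$year <= 2035]), numeric(1))
  expect_equal(fm$matrix$density_mean, mean(per_run))
  per_run_ratio <- vapply(runs, function(r)
    mean(r$grass_shrub_ratio[r$year >= 2025 & r$year <= 2035]), numeric(1))
  expect_equal(fm$matrix$ratio_mean, mean(per_run_ratio))
})

test_that("grid snapshots round-trip through plain CSV", {
  set.seed(76)
  g <- init_grid(12, 9, 0.5)
  g$clock$year <- 1987L; g$clock$season <- "JJA"
  path <- tempfile(fileext = ".csv")
  write_snapshot(g, path)
  back <- read_snapshot(path)
  expect_identical(back$species, g$species)
  expect_identical(back$sand, g$sand)
  expect_equal(back$growth, g$growth)
  expect_identical(back$age, g$age)
  expect_equal(back$clock$year, 1987L)
  expect_equal(back$clock$season, "JJA")
  expect_equal(back$width, 12L)
})

test_that("configurations load from YAML over the defaults", {
  cfg <- load_config(system.file("extdata", "ecology_reference.yaml",
                                 package = "ecodune"))
  expect_equal(cfg$transport$u_threshold, 5.1)
  expect_equal(cfg$grid$bulk_density, 2000)
  path <- tempfile(fileext = ".yaml")
  writeLines("transport:\n  u_threshold: 6.0", path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$transport$u_threshold, 6.0)
  expect_equal(cfg2$transport$p_d_bare, 0.6)  # untouched defaults remain
  wc <- load_wind_climatology(system.file("extdata", "wind_synthetic.yaml",
                                          package = "ecodune"))
  expect_s3_class(wc, "wind_climatology")
})
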