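test_that("deterministic trajectories follow the linear trend exactly", {
  sp <- scenario_spec(2017:2100,
                      c(DJF = 200, MAM = 90, JJA = 10, SON = 60),
                      c(DJF = -0.5, MAM = 0, JJA = 0, SON = 0))
  tr <- generate_precip_trajectory(sp)
  expect_equal(tr$precip_mm[tr$year == 2100 & tr$season == "DJF"], 158.5)
  expect_equal(tr$precip_mm[tr$year == 2017 & tr$season == "DJF"], 200)
  # sigma = 0 is exactly deterministic: repeated draws identical
  expect_identical(tr, generate_precip_trajectory(sp))
})

test_that("stationary sampling hits the stated mean and ranks variability", {
  means <- c(DJF = 180, MAM = 90, JJA = 20, SON = 80)
  splo <- scenario_spec(1:500, means, variability = "low")
  sphi <- scenario_spec(1:500, means, variability = "high")
  lo <- generate_precip_trajectory(splo, seed = 7)
  hi <- generate_precip_trajectory(sphi, seed = 7)
  # annual totals = sum of the four seasons by construction
  ann_lo <- tapply(lo$precip_mm, lo$year, sum)
  expect_equal(length(ann_lo), 500)

  # Monte-Carlo: DJF sample mean within 3 standard errors (sigma_season =
  # 30 / 2 = 15 mm)
  djf <- lo$precip_mm[lo$season == "DJF"]
  se <- 15 / sqrt(length(djf))
  expect_lt(abs(mean(djf) - 180), 3 * se)

  # low variability has the smaller interannual CV at equal means
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(ann_lo), cv(tapply(hi$precip_mm, hi$year, sum)))
  # truncation keeps totals non-negative even at high sigma
  expect_true(all(hi$precip_mm >= 0))
})

test_that("moving variability mode uses the per-year sigma table", {
  means <- c(DJF = 100, MAM = 50, JJA = 10, SON = 40)
  ref <- generate_precip_trajectory(
    scenario_spec(2000:2019, means, variability = "high"), seed = 3)
  sig <- moving_sigma(ref)
  spm <- scenario_spec(2000:2019, means, variability = "moving",
                       sigma_table = sig)
  tr <- generate_precip_trajectory(spm, seed = 4)
  expect_s3_class(tr, "climate_series")
  expect_error(
    generate_precip_trajectory(
      scenario_spec(1990:2019, means, variability = "moving",
                    sigma_table = sig), seed = 4),
    "missing entries")
})

test_that("equilibrium_year_forcing averages the 21-year window", {
  # ramp: window mean equals the midpoint value
  df <- expand.grid(year = 2000:2060, season = c("DJF", "MAM", "JJA", "SON"))
  df$precip_mm <- 100 + (df$year - 2000) * 2
  ser <- climate_series(df)
  f <- equilibrium_year_forcing(ser, 2030)
  expect_equal(unname(f), rep(100 + 30 * 2, 4))
  # constant series gives the constant
  df$precip_mm <- 55
  expect_equal(unname(equilibrium_year_forcing(climate_series(df), 2020)),
               rep(55, 4))
  # window exceeding the range names the missing years
  expect_error(equilibrium_year_forcing(ser, 2055), "2061")
})

test_that("moving_sigma matches the brute-force windowed sd", {
  df <- expand.grid(year = 2000:2019,
                    season = c("DJF", "MAM", "JJA", "SON"))
  df$precip_mm <- 50
  expect_true(all(moving_sigma(climate_series(df))$sigma == 0))

  # alternating 100/200 in DJF: centred 5-year windows
  df$precip_mm <- ifelse(df$season == "DJF",
                         ifelse(df$year %% 2 == 0, 100, 200), 30)
  ms <- moving_sigma(climate_series(df))
  v <- ifelse(2000:2019 %% 2 == 0, 100, 200)
  for (i in c(1, 3, 10, 20)) {
    idx <- max(1, i - 2):min(20, i + 2)
    expect_equal(ms$sigma[ms$season == "DJF"][i], sd(v[idx]))
  }
  expect_error(moving_sigma(climate_series(df[df$year < 2003, ])),
               "at least 5")
})

test_that("climate tables round-trip and malformed tables are rejected", {
  df <- expand.grid(year = 2001:2003, season = c("DJF", "MAM", "JJA", "SON"))
  df$precip_mm <- runif(nrow(df), 0, 150)
  ser <- climate_series(df)
  path <- tempfile(fileext = ".csv")
  write_climate_table(ser, path)
  back <- load_climate_table(path)
  expect_equal(back$precip_mm, ser$precip_mm)
  expect_equal(back$year, ser$year)

  # a single complete year is valid
  one <- climate_series(df[df$year == 2001, ])
  expect_equal(nrow(one), 4)

  # missing JJA season
  bad <- df[!(df$year == 2002 & df$season == "JJA"), ]
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_climate_table(path), "season")

  # negative precipitation reported with its row
  bad2 <- df; bad2$precip_mm[5] <- -3
  write.csv(bad2, path, row.names = FALSE)
  expect_error(load_climate_table(path), "negative")
})

test_that("wind events are seeded, Weibull-distributed and validated", {
  wc <- default_wind_climatology()
  set.seed(5); a <- sample_wind_event(wc, "DJF")
  set.seed(5); b <- sample_wind_event(wc, "DJF")
  expect_identical(a, b)
  expect_gte(a$speed, 0)
  expect_true(a$direction >= 0 && a$direction < 360)

  # closed-form Weibull mean: scale * Gamma(1 + 1/shape), 1e5 samples
  set.seed(6)
  sp <- replicate(1e5, sample_wind_event(wc, "SON")$speed)
  p <- wc$seasons$SON
  expect_lt(abs(mean(sp) / (p[["scale"]] * gamma(1 + 1 / p[["shape"]])) - 1),
            0.01)

  # degenerate direction table: single bin always drawn
  d1 <- rep(0, 16); d1[5] <- 1
  wc1 <- wind_climatology(wc$seasons, d1)
  set.seed(7)
  expect_equal(sample_wind_event(wc1, "MAM")$direction, 4 * 22.5)

  expect_error(wind_climatology(wc$seasons, rep(0.1, 16)), "unnormalised")
  expect_error(wind_climatology(list(DJF = c(shape = -1, scale = 2)),
                                d1), "DJF|positive")
})
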