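test_that("moisture growth increment follows the piecewise response", {
  cfg <- default_config()
  for (sp in c("grass", "shrub", "tree")) {
    harsh <- cfg$species[[sp]]$precip_harsh
    opt <- cfg$species[[sp]]$precip_opt
    expect_equal(moisture_growth_increment(sp, opt), 1)
    expect_equal(moisture_growth_increment(sp, opt + 50), 1)
    expect_lt(moisture_growth_increment(sp, 0), 0)
    expect_equal(moisture_growth_increment(sp, 0), -1)
    mid <- (harsh + opt) / 2
    expect_equal(moisture_growth_increment(sp, mid), 0.5)
    d <- moisture_growth_increment(sp, harsh + 0.25 * (opt - harsh))
    expect_equal(d, 0.25)
  }
})

test_that("neighbourhood stress is neutral when empty and distance-signed", {
  set.seed(20)
  g <- init_grid(21, 21, 0)
  expect_equal(neighbourhood_stress(g, c(11, 11)), 0.5)

  # one large neighbour: facilitation at shell 1, competition at shell 4
  g1 <- g; g1$species[11, 12] <- 3L; g1$growth[11, 12] <- 60
  g4 <- g; g4$species[11, 15] <- 3L; g4$growth[11, 15] <- 60
  s1 <- neighbourhood_stress(g1, c(11, 11))
  s4 <- neighbourhood_stress(g4, c(11, 11))
  expect_gt(s4, s1)
  expect_lt(s1, 0.5)  # close neighbour facilitates
  expect_gt(s4, 0.5)  # distant neighbour competes
})

test_that("neighbourhood stress equals the brute-force shell sum", {
  set.seed(21)
  g <- init_grid(11, 11, 0.4)
  cfg <- default_config()
  for (cell in list(c(6, 6), c(2, 9), c(1, 1))) {
    I <- 0
    for (k in 1:5)
      I <- I + cfg$kernel$shell_weights[k] *
        brute_ring_mean(g, cell, k, cfg)
    expect_equal(neighbourhood_stress(g, cell),
                 plogis(-cfg$kernel$squash_rate * I))
  }
})

test_that("sediment-balance stress saturates at the species tolerance", {
  cfg <- default_config()
  expect_equal(sediment_balance_stress(0, "shrub"), 0)
  tol <- cfg$species$shrub$sed_tol_slabs
  expect_equal(sediment_balance_stress(tol, "shrub"), 1)
  expect_equal(sediment_balance_stress(2 * tol, "shrub"), 1)   # deep burial
  expect_equal(sediment_balance_stress(-2 * tol, "shrub"), 1)  # exposure
  expect_equal(sediment_balance_stress(tol / 2, "shrub"), 0.25)
})

test_that("compound stress maps the weighted mean onto [p0, 1] monotonically", {
  cfg <- default_config()
  expect_equal(compound_stress(rep(0, 7)), cfg$stress$p0)
  expect_equal(compound_stress(rep(1, 7)), 1)

  # hand computation for a mixed vector
  v <- c(0.5, 1, 0.2, 0, 0.3, 0, 0)
  w <- c(0.3, 0.3, 0.1, 0.1, 0.1, 0.05, 0.05)
  S <- sum(w * v)
  r <- cfg$stress$squash_rate
  sq <- (plogis(r * (S - 0.5)) - plogis(-r / 2)) /
    (plogis(r / 2) - plogis(-r / 2))
  expect_equal(compound_stress(v, w),
               cfg$stress$p0 + (1 - cfg$stress$p0) * sq)

  # monotone non-decreasing in every component
  set.seed(22)
  for (i in 1:20) {
    v <- runif(7)
    j <- sample(7, 1)
    v2 <- v; v2[j] <- min(1, v[j] + 0.2)
    expect_gte(compound_stress(v2), compound_stress(v))
  }
  expect_error(compound_stress(rep(0, 7), weights = rep(1, 7)), "weights")
  expect_error(compound_stress(c(2, rep(0, 6))), "components")
})

test_that("vegetation step is deterministic and order-independent", {
  set.seed(23)
  g <- init_grid(11, 11, 0.6)
  g$fire_flag[2, 2] <- 1L
  g$pioneer[2, 2] <- 1L
  g$graze_stress[3, 3] <- 0.4
  g$sand[4, 4] <- g$sand[4, 4] + 4L
  cfg <- default_config()

  set.seed(31); a <- vegetation_step(g, 80, cfg)
  set.seed(31); b <- vegetation_step(g, 80, cfg)
  expect_identical(a, b)

  # synchronous update equals the independent per-cell oracle under
  # shared draws (hence independent of any iteration order)
  set.seed(32)
  draws <- list(die = matrix(runif(121), 11, 11),
                rec = matrix(runif(121), 11, 11),
                spc = matrix(runif(121), 11, 11))
  fast <- vegetation_step(g, 80, cfg, draws = draws)
  slow <- veg_oracle(g, 80, cfg, draws)
  expect_identical(fast$species, slow$species)
  expect_equal(fast$growth, slow$growth)
  expect_identical(fast$age, slow$age)
  expect_identical(fast$pioneer, slow$pioneer)
})

test_that("sustained optimal rain with only moisture stress grows everyone", {
  # kernel off, stress carried by precipitation alone, no background
  # mortality: every plant climbs to G_max and ages one season per step
  cfg <- default_config(
    kernel = list(shell_weights = rep(0, 5)),
    stress = list(weights = c(0, 1, 0, 0, 0, 0, 0), p0 = 0),
    recruitment = list(r_moisture = 0, r_facilitation = 0)
  )
  set.seed(24)
  g <- init_grid(15, 15, 0.5, config = cfg)
  g$growth[g$species > 0] <- 1
  g$age[g$species > 0] <- 1L
  ages0 <- g$age[g$species > 0]
  occ0 <- g$species > 0
  # 15 seasons keeps every plant below its lifespan cap (grass: 20)
  for (i in 1:15) g <- vegetation_step(g, 200, cfg)
  gmax <- c(10, 30, 60)
  expect_identical(g$species > 0, occ0)  # nobody died, nobody recruited
  expect_equal(g$growth[occ0],
               pmin(1 + 15, gmax[g$species[occ0]]))  # +1 unit per season
  expect_equal(g$age[occ0], ages0 + 15L)
})

test_that("prolonged zero rainfall collapses the population", {
  set.seed(25)
  g <- init_grid(20, 20, 0.9)
  for (i in 1:40) g <- vegetation_step(g, 0)
  expect_equal(sum(g$species > 0), 0)
})

test_that("burned ground recruits mostly grass under favourable rain", {
  set.seed(26)
  g <- init_grid(30, 30, 0.6, c(shrub = 0.8, tree = 0.2))  # shrub matrix
  fr <- apply_fire(g, default_config(species = list(
    shrub = list(burn_prob = 1), tree = list(burn_prob = 1))))
  g <- fr$grid
  expect_equal(sum(g$species > 0), 0)
  g2 <- vegetation_step(g, 150)
  rec <- g2$species[g2$species > 0]
  expect_gt(length(rec), 20)
  expect_gt(sum(rec == 1L), sum(rec == 2L))  # grass-led recolonisation
})
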