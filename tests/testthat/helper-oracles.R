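# Brute-force oracles, independent of the package's internal vectorised
# implementations.

# all cells at exactly Chebyshev distance k from `cell`, by full scan
brute_ring <- function(nr, nc, cell, k, periodic) {
  out <- NULL
  for (r in 1:nr) for (c in 1:nc) {
    dr <- abs(r - cell[1]); dc <- abs(c - cell[2])
    if (periodic) {
      dr <- min(dr, nr - dr); dc <- min(dc, nc - dc)
    }
    if (max(dr, dc) == k) out <- rbind(out, c(r, c))
  }
  out
}

# per-cell mean normalised biomass over ring k (bare cells count as zero)
brute_ring_mean <- function(grid, cell, k, config) {
  periodic <- identical(grid$boundary, "periodic")
  ring <- brute_ring(grid$height, grid$width, cell, k, periodic)
  if (is.null(ring)) return(0)
  bmax <- vapply(config$species, function(s) s$b_max, numeric(1))
  tot <- 0; n <- 0
  for (i in seq_len(nrow(ring))) {
    # under periodic wrap a lattice site can shelter the focal cell through
    # several images; the scan counts each site once, as shells() does
    sp <- grid$species[ring[i, 1], ring[i, 2]]
    b <- if (sp > 0) pathway_biomass(sp, grid$growth[ring[i, 1], ring[i, 2]],
                                     config) else 0
    tot <- tot + b / bmax[3]
    n <- n + 1
  }
  unname(tot / n)
}

# independent per-cell reimplementation of the seasonal vegetation update,
# looping cells one at a time from the frozen start-of-season state
veg_oracle <- function(grid, precip, config, draws) {
  nr <- grid$height; nc <- grid$width
  periodic <- identical(grid$boundary, "periodic")
  sp_par <- function(f) vapply(config$species, function(s) as.numeric(s[[f]]),
                               numeric(1))
  harsh <- sp_par("precip_harsh"); opt <- sp_par("precip_opt")
  bmax <- sp_par("b_max"); gmax <- sp_par("g_max")
  life <- sp_par("lifespan_seasons"); tol <- sp_par("sed_tol_slabs")
  w <- config$stress$weights
  kr <- config$kernel
  rc <- config$recruitment
  suit <- pmin(pmax((precip - harsh) / (opt - harsh), 0), 1)

  out <- grid
  for (r in 1:nr) for (c in 1:nc) {
    I <- 0; F12 <- 0
    for (k in 1:5) {
      rm_ <- brute_ring_mean(grid, c(r, c), k, config)
      I <- I + kr$shell_weights[k] * rm_
      if (k <= 2) F12 <- F12 + max(kr$shell_weights[k], 0) * rm_
    }
    sp <- grid$species[r, c]
    if (sp > 0) {
      B <- pathway_biomass(sp, grid$growth[r, c], config)
      sens <- min(max(1 - kr$sens_slope * B / bmax[3], 0), 1)
      s_nb <- plogis(-kr$squash_rate * I * sens)
      s_pre <- 1 - min(max((precip - harsh[sp]) / (opt[sp] - harsh[sp]), 0), 1)
      s_bio <- 1 - B / bmax[sp]
      s_age <- min(max((grid$age[r, c] - 0.75 * life[sp]) /
                         (0.25 * life[sp]), 0), 1)
      d_sand <- grid$sand[r, c] - grid$sand_ref[r, c]
      s_sed <- min((abs(d_sand) / tol[sp])^2, 1)
      s_grz <- min(max(grid$graze_stress[r, c], 0), 1)
      s_fire <- if (grid$fire_flag[r, c] > 0) 1 else 0
      S <- sum(w * c(s_nb, s_pre, s_bio, s_age, s_sed, s_grz, s_fire))
      rate <- config$stress$squash_rate
      lo <- plogis(-rate / 2); hi <- plogis(rate / 2)
      sq <- (plogis(rate * (min(max(S, 0), 1) - 0.5)) - lo) / (hi - lo)
      p <- config$stress$p0 + (1 - config$stress$p0) * sq
      if (grid$age[r, c] >= life[sp]) p <- 1
      if (draws$die[r, c] < p) {
        out$species[r, c] <- 0L; out$growth[r, c] <- 0; out$age[r, c] <- 0L
      } else {
        dg <- if (precip >= opt[sp]) 1
          else if (precip >= harsh[sp]) (precip - harsh[sp]) /
            (opt[sp] - harsh[sp])
          else -(harsh[sp] - precip) / harsh[sp]
        out$growth[r, c] <- min(max(grid$growth[r, c] + dg, 0), gmax[sp])
        out$age[r, c] <- grid$age[r, c] + 1L
      }
    } else {
      p_rec <- min(max(rc$r_base + rc$r_moisture * max(suit) +
                         rc$r_facilitation * max(F12, 0), 0), 1)
      if (draws$rec[r, c] < p_rec) {
        cnt <- numeric(3)
        for (k in 1:2) {
          ring <- brute_ring(nr, nc, c(r, c), k, periodic)
          for (i in seq_len(nrow(ring))) {
            s <- grid$species[ring[i, 1], ring[i, 2]]
            if (s > 0) cnt[s] <- cnt[s] + 1
          }
        }
        tot <- sum(cnt)
        bare_like <- tot == 0 || grid$pioneer[r, c] > 0
        ws <- numeric(3)
        for (k in 1:3) {
          base <- if (bare_like) rc$bare_prior[[k]]
            else (1 - rc$copy_blend) * cnt[k] / tot +
              rc$copy_blend * rc$bare_prior[[k]]
          ws[k] <- base * (suit[k] + rc$suit_floor)
        }
        u <- draws$spc[r, c] * sum(ws)
        ch <- if (u < ws[1]) 1L else if (u < ws[1] + ws[2]) 2L else 3L
        out$species[r, c] <- ch; out$growth[r, c] <- 1; out$age[r, c] <- 0L
        out$pioneer[r, c] <- 0L
      }
    }
  }
  out$fire_flag <- matrix(0L, nr, nc)
  out$graze_stress <- matrix(0, nr, nc)
  out$sand_ref <- out$sand
  out
}

# run n wind events of one season over a grid, returning grid and total
# eroded slabs (shared by transport property tests)
run_wind_events <- function(grid, n, season = "SON",
                            wind = default_wind_climatology(),
                            config = default_config()) {
  tot <- 0
  for (i in seq_len(n)) {
    ev <- sample_wind_event(wind, season)
    if (ev$speed <= config$transport$u_threshold) next
    vf <- compute_velocity_field(grid, ev, config)
    sh <- shadow_mask(grid, ev$direction, config)
    tr <- transport_iteration(grid, vf, ev$direction, sh, config)
    grid <- tr$grid
    tot <- tot + tr$tally$eroded
  }
  list(grid = grid, eroded = tot)
}
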