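grid:
  cell_size: 1.0
  slab_height: 0.1
  boundary: periodic
  sand_seed_range:
  - 5
  - 15
  bulk_density: 2000.0
clock:
  events_per_season: 20
species:
  grass:
    code: 1
    g_max: 10.0
    lifespan_seasons: 20
    b_max: 1.0
    h_max: 0.5
    h_exp: 0.7
    por_min: 0.16
    por_max: 0.2
    precip_harsh: 25.0
    precip_opt: 110.0
    sed_tol_slabs: 2.0
    burn_prob: 0.95
    palatability: 1.0
  shrub:
    code: 2
    g_max: 30.0
    lifespan_seasons: 160
    b_max: 5.0
    h_max: 1.5
    h_exp: 0.7
    por_min: 0.45
    por_max: 0.55
    precip_harsh: 10.0
    precip_opt: 60.0
    sed_tol_slabs: 5.0
    burn_prob: 0.6
    palatability: 0.3
  tree:
    code: 3
    g_max: 60.0
    lifespan_seasons: 400
    b_max: 20.0
    h_max: 6.0
    h_exp: 0.7
    por_min: 0.35
    por_max: 0.45
    precip_harsh: 40.0
    precip_opt: 120.0
    sed_tol_slabs: 8.0
    burn_prob: 0.25
    palatability: 0.0
kernel:
  shell_weights:
  - 0.4
  - 0.2
  - -0.3
  - -0.4
  - -0.5
  squash_rate: 4.0
  sens_slope: 0.8
stress:
  weights:
  - 0.1428571
  - 0.1428571
  - 0.1428571
  - 0.1428571
  - 0.1428571
  - 0.1428571
  - 0.1428571
  p0: 0.01
  squash_rate: 8.0
recruitment:
  r_base: 0.0
  r_moisture: 0.5
  r_facilitation: 0.3
  bare_prior:
  - 0.7
  - 0.2
  - 0.1
  copy_blend: 0.2
  suit_floor: 0.05
wind:
  recovery_coef: 7.0
  decay_rate: 5.0
  tree_mid: 0.5
  tree_rate: 12.0
  alpha: 0.5
  compression_cap: 1.5
transport:
  u_threshold: 5.1
  flux_coef: 0.0020408
  p_e_bare: 1.0
  p_e_veg: 0.2
  p_d_bare: 0.6
  p_d_veg: 1.0
  shadow_angle_deg: 15.0
  repose_bare_deg: 30.0
  repose_veg_deg: 40.0
  max_sweeps: 1000000
grazing:
  intake_gu_per_lsu_season: 20000.0
fire:
  season: SON
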