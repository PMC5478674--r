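---
title: "ecodune: model structure, parameterisation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecodune: model structure, parameterisation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodune)
```

## What the model is

`ecodune` simulates the coupled evolution of vegetation and wind-blown sand
in semi-arid (Kalahari-type) savanna landscapes on a square lattice. Each
cell (1 m by default) carries a sand column (discretised into 0.1 m slabs
over an immobile base), and at most one plant — a grass tussock, a shrub or
a tree. Three coupled processes run on two timescales:

1. **Wind and sediment transport** (per wind event, 20 events per season):
   a wind episode is sampled from a seasonal Weibull speed distribution and
   a 16-bin compass direction table; every plant casts a downwind wake
   corridor of reduced velocity; sand slabs are eroded where the local
   velocity exceeds the entrainment threshold, hop downwind and deposit
   probabilistically; slopes relax to the angle of repose.
2. **Vegetation dynamics** (once per season): each plant grows or shrinks
   along its species' growth pathway in response to the season's rainfall,
   accumulates a seven-component compound stress and dies with the
   resulting probability; bare cells recruit new plants.
3. **Disturbances** (seasonal, optional): spatially averaged grazing
   offtake proportional to a stocking rate, and probabilistic domain-wide
   fires on a fixed return interval.

The feedback loop is the point: vegetation pattern shapes the wind field,
which shapes sand movement, which (through burial/exposure stress) shapes
vegetation survival.

## Vegetation module

### Growth pathways

Plant state is a scalar "growth unit" count $g \in [0, G_{\max}]$ per
species. Biomass follows a normalised logistic in $g$, height a concave
power law $h = h_{\max}(g/G_{\max})^{0.7}$, porosity a gentle linear
increase. Defaults:

| species | $G_{\max}$ | lifespan (seasons) | $h_{\max}$ (m) | porosity | palatability |
|---------|-----------|--------------------|----------------|----------|---|
| grass   | 10        | 20                 | 0.5            | 0.16–0.20 | 1.0 |
| shrub   | 30        | 160                | 1.5            | 0.45–0.55 | 0.3 |
| tree    | 60        | 400                | 6.0            | 0.35–0.45 | 0.0 |

Grasses are fast and short-lived, trees slow and long-lived. Grasses are
bluff (low porosity), shrubs porous — this single contrast drives the
result that shrub-encroached landscapes shelter the surface less than
grass-covered ones at matched cover.

### Moisture response

The seasonal growth increment is piecewise linear in the season's rainfall
$P$ (mm): $+1$ growth unit at or above the species optimum, proportional
between the harsh threshold and the optimum, and negative below the harsh
threshold (down to $-1$ at $P = 0$), so prolonged drought walks plants back
down their pathways. Defaults (harsh, optimum), mm per season:
grass (25, 110), shrub (10, 60), tree (40, 140).

A deliberate design choice sits here. The "obvious" ordering — grass the
most drought-tolerant, then shrub, then tree — makes dry summers favour
*grass* survival, and the equilibrium grass:shrub ratio then *falls* as
wet-season (DJF) rainfall rises, the opposite of the shrub-encroachment
phenomenology this model family is built to capture. We therefore give
shrubs the conservative response (deep roots: low harsh threshold, early
saturation) and grasses the responsive one (shallow roots: they profit
from wet summers and suffer first in drought). With that ordering,
ramping DJF rainfall monotonically raises the equilibrium grass:shrub
ratio (tested), and trees keep the highest requirements, preserving the
rainfall-gradient pattern of more trees at wetter sites.

### Neighbourhood interaction

Each plant feels its neighbours over five concentric Chebyshev rings
(the extended Moore neighbourhood): mean neighbour biomass per ring,
weighted by the signed kernel (+0.4, +0.2, −0.3, −0.4, −0.5) — facilitation
close in, competition further out, the canonical vegetation-patterning
structure. The signed sum is squashed through a logistic onto a stress in
[0, 1]; an empty neighbourhood gives the neutral 0.5. Biomass sets both
the interaction a plant exerts and its sensitivity: the felt interaction is
scaled by $1 - 0.8\,B/B_{\max}^{tree}$, so seedlings and grasses feel
mature neighbours strongly while a mature tree barely notices anyone.

### Compound stress and mortality

Seven components, each in [0, 1]: neighbourhood, precipitation, biomass
(low biomass is precarious), age (ramping over the last quartile of the
lifespan), sediment balance (quadratic in net seasonal burial or exposure,
saturating at a species tolerance of 2/5/8 slabs), grazing offtake and
fire. Their weighted mean (equal weights by default) is squashed through a
normalised logistic onto a seasonal death probability with floor
$p_0 = 0.01$; all-zero stress gives exactly $p_0$, all-one stress gives 1.
Plants past their lifespan die outright.

### Recruitment

A cell bare at the start of the season recruits with probability
$0.5\,m + 0.3\,f$ where $m$ is the best species' moisture suitability and
$f$ the shell-1–2 facilitation. Species choice multiplies a context prior
by each species' suitability. On bare ground (no occupied cell within two
rings) — and on burned ground — the prior is the pioneer mix (grass 0.7,
shrub 0.2, tree 0.1). Inside a vegetated matrix the prior is 80%
neighbour-copying, 20% pioneer mix. Two consequences matter:

* Neighbour-copying favours whichever species persists longest, so an
  undisturbed landscape drifts slowly toward shrub dominance — shrub
  encroachment is the default trajectory, not an imposed one.
* Burned cells keep a persistent "pioneer" marker until recolonised, so
  post-fire ground recruits grass-first no matter what survived around it.
  Frequent fire therefore holds the system in a grassy state, and long
  fire-free periods let shrubs establish — the factorial structure the
  fire × grazing experiments probe (and the tests verify the sign of).

## Wind module

Each occupied cell casts a rectangular wake corridor, one footprint (one
cell) wide, of length $L = c\,h\,(1-\phi)$ with $c = 7$ (the
heights-to-recover scale of the wake literature), $h$ element height and
$\phi$ porosity. The velocity factor starts at the residual $\phi$ at the
element (a fully porous element removes no momentum) and recovers
exponentially for grasses and shrubs, logistically (slow initial rise) for
trees; both profiles are normalised to reach 1 at $x = L$. Overlapping
wakes combine by taking the minimum factor — the most sheltered state wins;
a product rule is the obvious alternative, but the minimum is conservative,
keeps the factor in [0, 1] by construction, and makes "removing a plant
never speeds up nothing" provable (a removal can only remove minima). The
incident direction snaps to the nearest of 16 compass bins and corridors
are rasterised by stepping one cell along the dominant axis per step, so no
grid rotation is needed. Airflow compression multiplies the velocity by
$\min(1.5,\; 1 + 0.5 \tan\theta)$ on upwind-facing slopes.

## Sediment module

Classic sand-slab cellular automaton mechanics, driven by the wind field:

* **Flux law**: the potential erosion from a cell is
  $q(u) = A\,(u - u_t)\,u^2$ slabs for $u > u_t = 5.1$ m s⁻¹ and zero
  otherwise — a semi-empirical cubic-type transport relation with the
  threshold measured for Kalahari sands. $A$ absorbs the event duration and
  is calibrated so that $u = 10$ m s⁻¹ over bare sand moves one slab per
  cell per event; only relative transport enters the landscape statistics.
  The continuous $q$ is discretised by stochastic rounding so the mean
  stays exactly on the law.
* **Polling without replacement**: every cell is visited exactly once per
  event in random order. Eroding cells (not shadowed, above threshold,
  passing the erosion-probability draw: 1 on bare cells, 0.2 under
  vegetation) release their slabs, which hop downwind one cell at a time,
  depositing at each visited cell with probability 0.6 on bare sand and 1
  on vegetated or shadowed cells.
* **Shadow zones**: cells lying below the 15° line descending downwind
  from any upwind crest are shadowed — no erosion, certain deposition.
* **Avalanching**: slabs move down the steepest 8-neighbour descent until
  no slope exceeds the angle of repose — 30° on bare cells, 40° where
  vegetation anchors the sand. Ties break at random.

Under periodic boundaries (the default) every eroded slab re-deposits, so
total sand is conserved exactly — the property the transport tests pin
down to the slab across a thousand random events. Mass bookkeeping uses a
bulk density of 2000 kg m⁻³.

## Climate forcing

The synthetic generator produces seasonal precipitation totals as a linear
trend (per-season baseline mean plus mm yr⁻¹ slope) plus independent
normal noise, truncated at zero rather than resampled (the bias is
negligible at the stated noise-to-mean ratios). Interannual variability
modes: *low* (σ = 30 mm annual equivalent) and *high* (σ = 160 mm) for
equilibrium experiments, and *moving* for transient runs, where the
per-season σ comes from centred 5-year moving windows of a reference
series (with edge shrinkage; the alignment of the window is not dictated
by anything physical, and centred is the symmetric choice). The
annual-equivalent σ is partitioned as σ_season = σ_annual/2, so four
independent seasonal deviates reproduce the annual variance.

What the generator emulates: declining seasonal trends with site-specific
means, the stated low/high variability regimes, and projection-like
year-to-year spread. What it does not: serial correlation (ENSO-like
multi-year wet/dry spells), co-variation between seasons, and any
temperature signal. Passing tests therefore show the model responds
correctly to mean and variance structure, not that it reproduces any
particular projected trajectory.

Wind climatology defaults (Weibull shape ≈ 2.1–2.3, scales 4.5–6.5 m s⁻¹,
a north-to-west-dominant direction table) are *synthetic* placeholders
shaped like southern-Kalahari conditions; measured parameters load from
YAML via `load_wind_climatology()`.

The three shipped site presets (`maun` 460 mm yr⁻¹, `tshane` 365,
`tsabong` 295, split DJF 45% / MAM 25% / JJA 5% / SON 25%, gently
declining) are likewise declared synthetic fixtures spanning the regional
north–south rainfall gradient.

## Experiments and statistics

* **Equilibrium**: stationary per-season forcing (e.g. the 21-year window
  mean around a key year from `equilibrium_year_forcing()`); statistics
  are means and coefficients of variation over the last 10 years,
  separated into wet (DJF) and dry (JJA) season, normalisable against a
  baseline run.
* **Transient**: an ensemble over a multi-decade forcing, each member with
  its own noise realisation; outputs are per-member series, the pointwise
  ensemble envelope, and 3-year moving averages.
* **Fire × grazing matrices**: a factorial of fire return intervals (10 /
  5 / 2 years) and stocking rates (0.001 / 0.01 / 0.06 LSU ha⁻¹),
  summarised over the 11-year windows centred on key years (2025–2035 for
  2030).
* **Threshold frequencies**: the fraction of seasonal records with a
  species' absolute cover strictly below a threshold (0.20 by default),
  plus the full cumulative-frequency curve. Strict inequality is a
  documented choice; with continuous covers the difference is measure
  zero, on a lattice it is visible only when cover sits exactly on the
  threshold.

"Population density" counts occupied cells over total cells; a tree is one
cell, not a crown footprint. The grass:shrub ratio with zero shrubs is
reported as `Inf` with an explicit flag, never as a silent division.

Grazing converts stocking rate to a seasonal growth-unit demand via a
per-LSU intake constant (20 000 growth units season⁻¹ by default) —
deliberately large relative to the 0.25–5.6 ha model domains so that the
0.06 LSU ha⁻¹ rate visibly suppresses grass at the reference
parameterisation, which is the calibration the disturbance design calls
for. Demand is taken grass-first (then shrubs; trees are not browsed) as a
uniform proportional offtake.

## Reproducibility and numerics

Every driver seeds per-(year, season, stage) RNG sub-streams derived from
one run seed, so all entry points are bit-reproducible (tested by running
them twice). The vegetation update is synchronous: everything is computed
from the frozen start-of-season state, so the result is independent of
cell iteration order — verified against an independent per-cell oracle on
11×11 grids. Avalanche relaxation carries a sweep guard that turns
non-convergence (impossible with consistent slab geometry, since every
move lowers potential energy) into an error rather than a hang.
Degenerate inputs are validated at the boundary: malformed species mixes,
unnormalised direction tables, missing seasons in climate tables and
empty cover series all raise named errors.

## Scales used by the test suite

The shipped tests run the full pipeline at reduced scale so the suite
stays fast: property tests on 11×11 to 30×30 grids; directional
experiments (drought collapse, the DJF rainfall ramp, the porosity
contrast, the fire × grazing gradient signs) on 50×50 grids over 15–50
model years. The 150×150 / 200-year configuration is the `paper` profile
of the command-line driver and runs unchanged — only wall-clock time
separates the two.

## Known limitations

No soil-moisture bucket, nutrient dynamics, seed dispersal kernels, CO₂
effects or temperature driver; fire is a domain-wide probabilistic event
without front propagation; grazing is spatially averaged, not an agent
model; no suspension, grain-size classes or crusting in the sand model; no
lateral wake spreading or turbulence. Cell size, slab height and the
initial sand-depth distribution are declared defaults, not measured
quantities.
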