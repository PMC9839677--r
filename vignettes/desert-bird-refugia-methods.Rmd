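---
title: "Methods: physiological climate-change impacts and refugia for desert birds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physiological climate-change impacts and refugia for desert birds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
behind them. The pipeline asks a physiological question about climate
change in the world's warm deserts: not "how much hotter will it get?"
but "how much more water will a bird have to evaporate to stay below its
lethal body temperature, and where does that risk concentrate relative to
where desert birds actually live?" It runs end to end on synthetic data
whose statistical structure mirrors the real inputs (gridded monthly
climate, range maps, habitat and elevation layers, protected areas), so
that every step can be tested against known constructions.

## The study system the generator emulates

`synth_config()` / `generate_landscape()` / `generate_climate()` /
`generate_species()` build a seeded toy world:

* a 40 x 25 grid of 50-km equal-area cells (the resolution of the gridded
  climate the analysis is designed for), with a coastline on the western
  edge and a seeded meander;
* monthly climatology with a latitudinal gradient, a seasonal cycle
  peaking in July north of the equator and January south of it, and a
  diurnal range and aridity that grow with distance from the coast;
  vapour pressure is tied to night-time temperature and aridity so that
  hot afternoons have desert-like relative humidities (10-25%);
* interannual variability as an annual temperature anomaly (sd 0.8 °C)
  shared by `tmax` and `tmin` and by all months of a year, drawn
  independently per pixel, year and period. The sd is a modelling choice
  (the variance structure of 30-year hottest-month series is not otherwise
  pinned down) and is exposed in the configuration. Radiation, wind,
  vapour pressure and precipitation keep their climatology across years,
  so a zero-warming, zero-noise configuration reproduces the current
  period exactly;
* a warming field `delta * (1 + 0.3 * normalized coast distance)`,
  renormalized so its area mean is exactly the configured global delta
  (2 or 4 °C) — continental interiors warm more than coasts; the future
  vapour pressure rises by 3% per degree (slight drying in relative
  terms);
* ~150 species with log-normal masses (median 39 g), contiguous ranges
  grown from desert-biased seed cells with log-normal sizes spanning
  orders of magnitude (2 to ~1000 cells), habitat preferences biased to
  desert codes, and ordered elevation limits;
* six longitudinal realm bands and a patchy protected-area mask near the
  configured 10% coverage.

What the generator does *not* emulate matters for interpretation: there
is no topographic climate correction, no soil moisture (the bird model
has no soil node), no ENSO-like temporal autocorrelation, and — most
importantly — humidity, wind and radiation co-vary smoothly with the
same aridity surface that drives temperature. In real deserts these
decouple (coastal fog deserts, monsoon edges), which is what makes
physiology-based impact maps diverge from air-temperature maps. In the
toy system the two stay strongly correlated, so the map-comparison
statistics (weighted Jaccard, under-/over-protection) mostly quantify
agreement; passing tests demonstrate the machinery, not the real-world
size of that divergence.

## Monthly climate to hourly microclimate

For each pixel the analysis uses the hottest month — July at and north of
the equator, January south of it (the equator is assigned to the northern
rule) — and one representative mean-climate day per year and month, since
the water-loss metrics are defined on an average day of that month.

* `monthly_to_daily()` interpolates 12 monthly values to 365 days with a
  periodic cubic spline anchored at mid-month days, continuous across the
  year boundary (available for workflows that need full seasons; the
  hottest-month pipeline reads the representative day directly, which
  coincides with the spline at its anchors).
* `diurnal_cycle()` is a Parton-Logan-type curve: a half-sine rise from
  `tmin` at sunrise to `tmax` at solar noon + 1 h, sinusoidal decline to
  sunset, and exponential decay (time constant 4 h) overnight back to
  `tmin` at the next sunrise. Day length comes from solar geometry at the
  pixel's latitude. Sunrise, sunset and the peak are snapped to whole
  hours so that the 24-value series attains `tmin` and `tmax` exactly —
  a discretization convention that makes the series' extrema testable to
  machine precision.
* `hourly_humidity()` holds vapour pressure constant over the day and
  converts with the Magnus saturation curve
  `e_sat(T) = 0.61094 exp(17.625 T / (T + 243.04))` kPa, capped at 100%.
* `clear_sky_radiation()` uses `S = S0 τ^(1/cos z) cos z` with
  `S0 = 1361` W/m² and transmittance `τ = 0.7`;
  `hourly_radiation()` rescales the clear-sky profile by the clear-sky
  fraction (observed monthly mean over modelled clear-sky mean, capped at
  1), so the returned profile integrates back to the observed mean.
* `build_microclimate()` assembles the hour-by-hour drivers at the
  bird's 1.5-m perch (taken as screen height: no vertical air-temperature
  profile, and the monthly wind is used for all hours). Sky radiant
  temperature follows Swinbank clear-sky emissivity
  (`ε = 9.37e-6 T_K²`); ground radiant temperature is air temperature
  plus 0.02 °C per W/m² of incident solar. Shade multiplies the solar
  flux on the animal and on the ground by (1 − shade) and changes nothing
  else, so open and shaded microclimates coincide at night.

## The endotherm water-balance model

The bird is a prolate ellipsoid (semi-axis ratio 1.1 at rest, up to 3
when stretching) of volume mass/density, with exact ellipsoid surface
area and characteristic dimension V^(1/3). Heat flows through two nodes:

* core → skin through a flesh shell (thickness half the semi-minor axis,
  conductivity 0.412–2.8 W/mK, the control of cascade stage 3);
* skin → plumage surface through the plumage layer (conductivity
  0.028 W/mK over depth × ptiloerection multiplier, stage 1);
* surface ↔ environment by forced convection (`Nu = max(2, 0.35 Re^0.6)`
  on V^(1/3)), longwave exchange with equal sky and ground view factors
  (emissivity 0.95), and absorbed shortwave (absorptivity 0.85 on a
  posture-independent silhouette equal to half the rest-shape surface —
  stretching increases convective and radiative surface but not the
  intercepted beam).

Water leaves by two routes. Respiratory: ventilation is the oxygen
demand of the current metabolic heat (20.1 J per mL O₂ at 20.94% O₂ and
0.2 extraction), multiplied by the respiratory multiplier; expired air is
saturated at core temperature (no nasal counter-current recovery — a
conservative choice), inspired vapour comes from ambient humidity.
Cutaneous: skin vapour at the baseline wetness fraction crosses the
plumage air layer (depth/D_vap, D_vap = 2.5e-5 m²/s) and the boundary
layer (Lewis relation) in series. The series path matters: with a
bare-skin coefficient alone, sleeking the plumage cools the skin and
water loss *falls* slightly as air warms below the panting onset; routing
the vapour through the plumage restores the expected monotone response
and is the more physical description. Latent heat is fixed at 2.406 kJ/g.

Basal metabolism is the passerine allometry `c1 M^c2` with defaults
`c1 = 0.045`, `c2 = 0.684` (W, M in g; ≈0.55 W at 39 g). The template
bird's plumage values (6 mm depth at 39 g) are configurable stand-ins for
measured values; the small and large model birds (13 g, 185 g) scale
plumage depths and feather lengths by `(M/39)^(1/3)` and re-evaluate the
allometry, all other parameters copied.

### The thermoregulatory cascade as a state space

Under heat load the model bird responds in order: (1) reduce
ptiloerection (multiplier 1 → 0.5), (2) stretch the body (ratio
1.1 → 3), (3) raise flesh conductivity (0.412 → 2.8 W/mK), (4) raise
core temperature (41 → 44 °C) and respiratory rate (1 → 7.5× resting)
together as one linearly coupled control, and (5) raise skin wetness
(baseline 0.02 → 1) as the implicit closure. We formalize the reachable
states as: at most one partially engaged stage, any mix of fully engaged
and skipped stages below it, and resting stages above it. The solver
enumerates this family — 31 one-dimensional balance solves — and returns
the state with minimal hourly water loss whose heat-balance residual is
within tolerance (1e-5 W by default; the acceptance bound is 1e-4 W). A
stage comes out "skipped" exactly when engaging it would not pay —
typically when the air is hotter than the body surface, where a sleeker
coat, a stretched posture or a flushed skin would *add* heat; its rest
value is then its heat-dissipating limit, which is how the ordered-
cascade invariant ("a stage engages only after the previous ones are at
their dissipating limits") is preserved.

Below thermoneutrality the cascade reverses: the only stage with room to
reverse is baseline skin wetness, which is shed toward zero first; if the
bird is still losing heat, metabolic rate rises above basal (up to 10×;
beyond that the state is flagged as an unmet cold load rather than
silently clipped, and unmet heat loads at full wetness and 44 °C are
flagged the same way).

Numerics: the two node temperatures are solved by a damped 2-D Newton
iteration with an analytic Jacobian (falling back to nested
false-position bracketing near the evaporation kink), and each stage
control by Illinois false-position on the residual. Tie-breaks are by
enumeration order; degenerate environments (radiant temperatures far
from air, zero wind) are handled by the free-convection floor and wide
brackets. Baseline wetness defaults to 0.02 — about a third of resting
TEWL is cutaneous for the 39-g bird, at the low end of what is reported
for arid-zone passerines; with substantially larger baselines the dry
adjustments become so water-expensive that the minimal-water solution
pants before saturating them, which would distort the classical response
order.

`hourly_water_loss()` solves every hour in the open and in 90% shade and
takes the per-hour minimum (shade-shifting); an open-only mode keeps the
bird exposed. `respirometry_curve()` runs the same solver at chamber
conditions (wind 0.1 m/s, RH 5%, no radiation, radiant temperatures equal
to air temperature) to produce body-temperature and water-loss curves
against air temperature.

## Impact metrics and statistics

* TEWL is the daily sum of hourly losses (g/day); ADR is the maximum
  water lost in any 3 consecutive hours of the day as a percentage of
  body mass (22 windows, no wrap across midnight, because the metric is
  defined on a single average day); ADR ≥ 15% is flagged lethal.
* Climate-change impact per pixel is the overlap of Gaussian kernel
  density estimates of current versus future yearly values (Silverman's
  bandwidth per sample, 512 grid points spanning both samples ± 3 pooled
  bandwidths). Each density is renormalized to unit mass on the grid so
  identical samples give exactly 1; zero-variance samples get a floored
  bandwidth (1e-6 |mean| + 1e-9), and essentially disjoint samples short-
  circuit to 0. Lower overlap means larger impact. Mean changes
  (future − current) accompany the overlaps.
* Realm comparisons use Kruskal-Wallis H (with tie correction, via
  `stats::kruskal.test`) and the effect size ε² = H/(n−1); map pairs are
  compared with Pearson correlation over shared valid pixels and with the
  weighted Jaccard index Σ min(x,y) / Σ max(x,y), which reduces to the
  ordinary Jaccard on 0/1 masks.

## Diversity, refugia and protection

Warm desert pixels are those with a desert habitat code and under 500 mm
annual precipitation. Species ranges are refined to Area of Habitat
(range ∩ suitable habitat codes ∩ elevation limits); species with ≥ 90%
of their AOH in desert are the desert birds (the boundary is implemented
inclusively — exactly 90.0% is retained — and is configurable, since
"more than 90%" and "≥ 90%" both appear in common usage). Diversity is
rarity-weighted richness: each species contributes 1/AOH-area to every
cell it occupies, so the map-wide sum equals the species count exactly —
a conservation law the tests exploit. Species are split into small/
medium/large at the mass tertiles, the three model birds (13/39/185 g)
represent the classes, and per-class impact maps are averaged per pixel
weighted by the number of species in each class.

Refugia are desert pixels with relatively high diversity and low impact
within their realm. Thresholds are within-realm linear-interpolation
percentiles over valid desert pixels with a strict ">" at the cut (the
"top 25%" reading). Two combination rules are provided, because the
source material supports both readings: the default requires diversity
AND (TEWL overlap OR ADR overlap) above the threshold; an all-three-AND
mode applies one threshold to all three layers. The floating threshold
is the largest percentile (descending scan in 0.1 steps, which keeps
"largest" well-defined under ties) whose refugia cover at least the
target fraction (default 5%) of the realm. Protected-area coverage is
the percentage of refugial area inside the PA mask (assumed already
restricted to strict management categories on ingestion); the
physiology-versus-air-temperature comparison reports under-protection
(physiological refugia missed by the Tair map) and over-protection (Tair
refugia absent from the physiological map), each relative to its own
reference mask — one consistent reading of denominators that are not
otherwise fixed.

The sensitivity suite re-runs the reference bird at a sample of desert
sites under low/high values of solar absorptivity, plumage depth,
baseline wetness and the metabolic coefficient (plus the min-water and
max-water combinations, with each parameter's direction probed at a hot
reference condition) and scores the consistency of the top-25% safe
sites, ties broken by site index.

## Problem sizes and reproducibility

The default toy run — chosen as a size at which every property of the
full analysis is exercised while a complete double run (for the
determinism check) stays comfortable on a single core — uses the
40 x 25 grid, 2 periods × 10 years, 3 model birds and ~150 species;
physiology is solved on desert pixels only (≈600 of 1000). Every random
draw descends from one integer seed (per-stage fixed offsets), the C++
solver is deterministic, and the run writes CSV tables plus a manifest
with MD5 checksums, so identical configurations produce byte-identical
outputs. The acceptance script (`scripts/acceptance.R`) repeats the full
pipeline and the sensitivity suite from scratch at a caller-supplied
seed.

## Known limitations

Steady-state hourly balances ignore heat storage and transient
hyperthermia strategies; there is no torpor, no nocturnal activity
budget, and no behavioural option beyond the open/shade pair. The
longwave environment and the diurnal curve family follow standard simple
forms rather than a calibrated microclimate engine, and wind is constant
over the day at animal height. The synthetic world's strong coupling
between temperature and the other drivers compresses the difference
between physiological and air-temperature impact maps. Results on the
toy system demonstrate correctness of the machinery and qualitative
behaviour — they are not projections for any real desert.
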