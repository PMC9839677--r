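# desertrefugia

Physiologically explicit assessment of climate-change impacts on desert
birds, and identification of climate refugia worth protecting.

Rising air temperature is a blunt measure of risk for desert birds: what
kills them is the water cost of staying cool. A bird in the heat must
evaporate water to keep its body below a lethal core temperature
(~44 °C), and it dies of acute dehydration long before it starves. This
package implements that logic as a tested pipeline:

1. **Microclimate** — monthly gridded climate (tmax, tmin, vapour
   pressure, shortwave, wind) is downscaled to hourly conditions at a
   perched bird's height for the hottest month (July in the Northern
   Hemisphere, January in the Southern), in the open and in 90% shade.
2. **Endotherm water balance** — a steady-state two-node heat balance of
   a model bird solves, hour by hour, the ordered thermoregulatory
   cascade: sleek the plumage → stretch the body → raise flesh
   conductivity → raise core temperature (≤ 44 °C) coupled with
   respiratory rate (≤ 7.5× resting) → recruit cutaneous evaporation.
   The solver returns the minimal-water steady state; the bird shifts
   between open and shade to minimize hourly loss. Three model birds
   (13 g, 39 g, 185 g) represent the small/medium/large desert species,
   with size traits scaled by (M/39)^(1/3).
3. **Impact metrics** — TEWL (total evaporative water loss, g/day) and
   ADR (maximum water lost in any 3 consecutive hours, % of body mass;
   ≥ 15% is lethal). Climate-change impact per pixel is the overlap of
   kernel density estimates of current vs future yearly values — lower
   overlap, higher impact.
4. **Diversity** — species ranges refined to Area of Habitat, desert
   birds selected (≥ 90% of AOH in warm desert: desert habitat and
   < 500 mm annual rain), and rarity-weighted richness
   RWR(cell) = Σ_species 1/AOH.
5. **Refugia** — per desert realm, pixels with high diversity and low
   impact above a fixed 75th-percentile threshold or a floating
   threshold guaranteeing ≥ 5% of realm area; overlap with protected
   areas; comparison of physiology-based vs air-temperature-based maps
   (weighted Jaccard, under-/over-protection); safe-site consistency
   under physiological parameter perturbations.

A seeded synthetic-data module generates the full study system (climate
grids for a current and a +2 °C / +4 °C period, species, landscapes,
protected areas), so the whole analysis runs end to end, deterministically,
with no external data.

## Worked example

```r
library(desertrefugia)

# a 39-g desert passerine on a hot July day (tmax 42, tmin 26 C, lat 25 N)
bird <- make_model_bird(39)
site <- list(latitude = 25, month = 7, tmax = 42, tmin = 26,
             vapor_pressure = 1.2, shortwave = 320, wind = 2)
open  <- build_microclimate(site, 0)
shade <- build_microclimate(site, 0.9)

day <- hourly_water_loss(open, shade, bird)
tewl(day)                  # 9.16 g/day with shade-shifting
tewl(hourly_water_loss(open, NULL, bird))   # 11.65 g/day if stuck in the open
adr(day)                   # 5.96 % of body mass in the worst 3 h
lethal_dehydration(adr(day))  # FALSE: survivable, but ~24% of body mass/day

# simulated respirometry: panting onset ~30 C, Tb 43.3 C at Ta = 45 C
respirometry_curve(bird, c(25, 35, 45))
```

The daily totals say a bird that cannot reach shade loses ~27% more
water; at 45 °C in a metabolic chamber the model bird is panting hard
(respiratory rate ~6× resting) with its core pushed to 43.3 °C.

The full analysis is organized as numbered drivers:

```sh
Rscript analysis/01_simulate.R      # synthetic climate, species, landscape
Rscript analysis/02_physiology.R    # respirometry + example day budgets
Rscript analysis/03_impact.R        # per-pixel overlap/change maps -> results/run/
Rscript analysis/04_diversity.R     # AOH funnel, RWR
Rscript analysis/05_refugia.R       # fixed/floating refugia, PA coverage
Rscript analysis/06_sensitivity.R   # safe-site robustness to parameters
```

On the default seed the toy world has 591 desert pixels and 137 desert
birds; the fixed 75th-percentile rule marks 6.6% of desert area as
refugia of which ~10% is protected, the floating rule secures ≥ 5% per
realm at thresholds between the 70th and 86th percentiles, and the
top-25% safe sites are re-identified with ≥ 93% consistency under
perturbed physiological parameters.

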