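---
title: "Assessing rangeland carrying capacity from energy supply and demand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing rangeland carrying capacity from energy supply and demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangecap)
```

## The energy-balance model

`rangecap` treats a grazing system as a yearly energy budget per grazing
area. The demand side is the metabolizable energy requirement (MER) of the
herds counted in seasonal censuses; the supply side is the metabolizable
energy content (MEC) of the forage accessible to those herds. Their ratio is
the utilization intensity, and the 40% sustainable-utilization level turns
forage supply into a carrying capacity.

### Demand

Daily energy expenditure is the allometric field-metabolic-rate prediction
for free-ranging mammals, `ME = a · BM^b / 1000` MJ/day with body mass `BM`
in grams and defaults `a = 4.82`, `b = 0.734`. Using *end-of-season* body
masses folds seasonal weight gain (spring/summer fat storage) and loss
(winter catabolism) into the daily rates, so no separate energy partitioning
into maintenance, lactation or locomotion is attempted — the elevated-MER
scenario (a flat ×1.3 on all livestock except yak, which is evolutionarily
adapted to cold high-altitude environments) subsumes those effects.

The grazing year is partitioned into early summer (May–June, 61 d), high
summer (July–September, 92 d) and winter (October–April, 212 d), a non-leap
calendar summing to 365 days. Winter belongs to the preceding growing-season
year: an early-spring winter census counts toward the previous year. The
default body-mass table is back-derived by inverting the allometric equation
at the reference daily requirements; this guarantees that
`daily_requirement_table()` reproduces those values exactly while remaining
fully overridable with field-weighed masses (`annual_requirement()`
reproduces the published annual sums within 2 MJ, the rounding of the
printed dailies).

Winter censuses exist only for a few reference years; other winters are
imputed per species as summer count × mean(winter/summer) over the
reference years, pooled over age classes (the winter census tables do not
resolve ages), rounded half-up, and flagged `imputed`. Cattle and camels
graze high summer only, so they never receive winter records. Imputed
historical winters are estimates, not observations, and the package never
uses them as test anchors.

Wild herbivores (marmots at 16.3 individuals/km² of vegetated habitat;
argali and ibex) graze without area restrictions: their population is
density × total vegetated area, distributed across areas in proportion to
vegetated hectares. Marmots hibernate; the active window is taken as
May–September (61 + 92 active days, none in winter). That window is a
documented assumption, configurable through the species profile, since only
the fact of hibernation — not its dates — is established for the study
system. Wild-ungulate densities and seasonal masses are *synthetic
placeholders* (default density 0): no regional survey values are bundled,
so the wildlife scenario only becomes quantitative once the user supplies
densities. Wildlife demand is never scaled by the elevated-MER scenario.

### Supply

Per 10 m pixel, `MEC = max(standing − adjustment, 0) × productivity ratio ×
consumable fraction × forage quality` in MJ/ha/year. The community
parameters are forage qualities of 9.4 MJ/kg DM (riparian grasslands, Salix
riparian communities), 9.1 (salt grass, alpine grasslands) and 6.3
(dwarf-shrub deserts and steppes); consumable fractions of 0.5 for the woody
dwarf-shrub communities and 0.8 elsewhere; and an exclosure-derived
productivity ratio converting standing biomass to annual production. No
winter reduction of forage quality is applied — measured seasonal
differences in these communities are small. Non-vegetated classes (water,
snow/ice, rock and scree) contribute zero and are excluded from all
denominators.

Standing biomass comes from a 500-tree random-forest regression
(`randomForest` with otherwise default parameters; tuning changes little
with this method) on eight vegetation indices: WDVI and a green/red-adjusted
variant, a B8a/B3 ratio, two red-edge normalized differences, MTCI, and the
soil-adjusted SACRI/MSACRI in the short-wave infrared. The bare-soil line
(α, β) has *no default*: it is scene-specific and must be supplied.
Predictions are clamped at zero. Model error is estimated by 100-repeated
10-fold *spatial* cross-validation; since the exact blocking rule behind
published spatial CV frameworks varies, folds here are k-means clusters of
the plot coordinates, re-drawn each repeat with repeat-indexed seeds. Plots
are sorted into a canonical coordinate order before clustering so results
are invariant to input row permutations. Units: field plots in kg DM/100 m²,
rasters in kg DM/ha (×100 at the plot–raster boundary), MEC in MJ/ha/year.

The conservative-biomass scenario subtracts half of the mean validation MAE
(converted to kg DM/ha) from the standing-biomass raster *before* the
productivity ratio is applied — the adjustment targets modeled biomass, not
derived production. The subtraction clamps at zero.

The productivity ratio can be pooled globally (default) or per community.
With very few surviving exclosure pairs either choice is defensible; both
are provided and neither is asserted as canonical. Single-pair groups are
flagged low-confidence.

### Accessibility

Seasonal masks implement the transhumance rules: early summer, pixels below
35% mean fractional snow cover (FSC), all species; high summer, small stock
below 4500 m a.s.l., large stock everywhere except winter-use areas; winter,
only areas with winter camps and mean winter FSC below 78%. All thresholds
use strict inequality — "below" excludes boundary pixels — and are
configurable. The 35% spring threshold is applied to a seasonal *mean* FSC
composite (whether it should apply per composite is unresolved; the mean is
assumed and the aggregation happens upstream). Winter masks never consult
the DEM; large-stock summer masks never consult FSC. Coarse FSC fields
(e.g. 500 m satellite composites) are transferred to the 10 m grid by
nearest-neighbour assignment, preserving values exactly.

Grazing-area polygons are inputs (catchment delineation is upstream of this
package); pixels are assigned to the single polygon containing their centre,
and overlapping polygons are rejected — the areas are exclusive management
units.

### Assessment

Annual supply per area sums MEC over pixels accessible in *at least one*
season, counting each pixel once however many seasons it can be reached in:
the budget compares yearly production with yearly demand, and production is
not additive across seasons. Demand from a season in which an area has no
accessible pixels is retained (the animals were counted there); dropping it
would silently move energy between areas. Utilization is 100 × demand /
supply; classification uses strict `>`: exactly 40% is sustainable, above
40% unsustainable, above 100% over-potential. Region aggregates (mean
utilization, percent of area unsustainable) are computed over vegetated,
ever-accessible pixels, each carrying its area's mean rate. Per-area rates
are reported at full precision; tabular outputs round to the conventions of
community-level reporting (two decimals for animals/ha).

## The synthetic landscape

Because the full-resolution rasters and censuses of a real study region are
not redistributable, the generator fabricates a study system with known
ground truth:

* a DEM spanning 3000–6000 m with smooth relief;
* communities arranged along the altitudinal gradient (riparian/Salix belt
  lowest, then salt grass, dwarf-shrub steppe, alpine grassland, bare rock
  above ~5250 m), with community-mean annual productions of 1729/1982/641/
  461/900 kg DM/ha matching regional survey magnitudes;
* reflectance bands built from a soil-brightness field plus a
  vegetation-fraction signal, so the eight indices carry a recoverable
  biomass signal (correlation of WDVI with true production above 0.6 at the
  default noise of 0.008 reflectance units);
* FSC ramping linearly with elevation, snowier in winter than spring, so
  that valley areas are winter-accessible (below 78%) and high areas are
  not;
* rectangular grazing areas tiling the extent, winter camps assigned to the
  lowest-lying areas;
* censuses *inverted from the demand model*: herd sizes (55% sheep, 38%
  goats, 7% yak by headcount; 80/20 adult/young) are chosen so annual MER
  approximates a target utilization of each area's true supply, herds in
  camp-less areas being present in the two summer seasons only.

The closed loop — generate, assess, compare with the configured target —
recovers utilization to within integer-herd rounding (well under one
percentage point at the default 200 × 200 grid, where herds are tens to
hundreds of animals). What this does and does not show: it validates the
bookkeeping (demand, MEC, masking, zonal aggregation) end to end, but the
generator does not emulate atmospheric effects, cloud gaps, sensor
geometry, mixed pixels at community boundaries, georeferencing error, or
herder behaviour within areas, so passing tests do not certify performance
on real imagery or real censuses.

## Numerical and representation choices

* Rasters are an in-package grid class (matrix + origin + square pixel size
  + CRS label) with plain-text ESRI ASCII grid I/O; vectors are GeoJSON;
  tables are UTF-8 CSV. Round trips are value-exact at 15 significant
  digits. All layers of a bundle must share one CRS, checked before any
  computation.
* Division by zero in index denominators yields nodata, not an error;
  nodata in any input propagates to MEC and is excluded from zonal sums.
* Imputed counts round half-up (`floor(x + 0.5)`); demand always uses
  integer headcounts.
* The random-forest seed is set immediately before each fit, and spatial-CV
  repeats use `seed + r`, so identical calls are bit-reproducible.
* Degenerate inputs fail loudly and specifically: missing body mass names
  the (species, age, season) cell; an unparameterized vegetated class names
  the class; overlapping polygons name both areas; configuration files
  report *all* schema violations in one aggregated error.

## Problem sizes

The test suite exercises 80 × 80-pixel landscapes for most properties and
one 200 × 200 system for the closed loop; spatial CV runs with 2 repeats in
tests and 10 in the acceptance script (the repeat count only narrows the
averaging of the metrics; the function default remains 100). The full suite
runs in well under a minute on one core.

## Known limitations

Grazing-area borders are treated as hard, though real herds cross them when
forage gets scarce late in summer; within-area gradients (camp proximity,
stock paths) are not modelled, so utilization is uniform within an area.
Snow is represented by cover fraction, not depth. The productivity ratio
rests on few exclosure pairs and is the weakest-supported parameter; the
conservative-biomass scenario exists precisely to bound its influence.
Forage quality is constant per community, so species-composition change
under grazing pressure is invisible to the model.
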