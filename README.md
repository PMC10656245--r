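# rangecap

Carrying-capacity and utilization-intensity assessment for cold dryland
rangelands.

Mountain transhumance systems — herders moving sheep, goats, yaks, cattle and
camels between spring, summer and winter pastures — are hard to assess with
the usual coarse stocking-rate statistics. `rangecap` implements a
high-resolution energy-balance pipeline for such systems: it compares the
**metabolizable energy requirement (MER)** of the herds counted in seasonal
livestock censuses with the **metabolizable energy content (MEC)** of the
forage each grazing area can actually offer, after accounting for vegetation
community, forage quality, consumability, annual productivity, and seasonal
accessibility limits from snow cover and elevation.

## The model

Daily energy expenditure of a free-ranging herbivore follows the allometric
field-metabolic-rate prediction

```
ME = 4.82 · BM^0.734 / 1000        [MJ/day, BM in g]
```

evaluated at end-of-season body masses so that seasonal weight gain and loss
are included. Herd MER per grazing area is headcount × daily rate × season
length, summed over the three grazing seasons (early summer May–June, 61 d;
high summer July–September, 92 d; winter October–April, 212 d).

Forage supply per pixel (10 m grid) is

```
MEC = standing biomass · productivity ratio · consumable fraction · forage quality
```

in MJ/ha/year, with standing biomass from a random-forest regression on eight
soil-adjusted, red-edge and short-wave-infrared vegetation indices (validated
by repeated spatial cross-validation), the productivity ratio from exclosure
pairs, consumable fractions of 0.5 (woody dwarf-shrub communities) or 0.8
(all others), and community forage qualities of 9.4/9.1/6.3 MJ/kg DM.
Seasonal accessibility masks restrict grazing to pixels below 35% fractional
snow cover in spring, below 4500 m for small stock in high summer, and to
winter-camp areas below 78% mean winter snow cover in winter.

Per grazing area and year:

* **utilization intensity** = 100 · MER / MEC (percent),
* **grazing potential** = MEC per ha / annual MER per animal (animals/ha),
* **carrying capacity** = grazing potential × 0.40 (the sustainable
  utilization level for dry high-mountain rangelands),

with areas classed `sustainable`, `unsustainable` (> 40%) or
`over_potential` (> 100%). Scenarios cover 30% elevated requirements for all
species except yak, conservatively lowered biomass, added wildlife (marmots
and wild ungulates), and dropping winter grazing.

Because no full-resolution rasters or censuses are distributable, the package
ships a synthetic-landscape generator (`generate_bundle()`) producing DEM,
community map, biomass, reflectance bands, snow-cover fields, grazing areas
and censuses with known ground truth, so the whole pipeline is testable end
to end.

## Worked example

```r
library(rangecap)

# annual requirement of an adult yak kept on pasture year-round
annual_requirement("yak")
#> [1] 13788.14

# community-level potential and capacity (riparian grasslands, yak)
mec <- bigpamir_mec_means()
pot <- grazing_potential(mec[["riparian_grassland"]], annual_requirement("yak"))
round(c(potential = pot, capacity = carrying_capacity(pot)), 2)
#> potential  capacity
#>      0.94      0.38

# end-to-end on a synthetic landscape calibrated to 40% utilization
bundle <- generate_bundle(landscape_config(), seed = 1, target_utilization = 0.4)
res <- run_scenario(bundle$inputs, scenario_config("basic"))
res$results[, c("area_id", "utilization_pct", "class")]
#>   area_id utilization_pct         class
#> 1 area_01           39.49   sustainable
#> 2 area_02           40.49 unsustainable
#> 3 area_03           39.61   sustainable
#> 4 area_04           40.16 unsustainable
res$region$mean_utilization_pct
#> [1] 39.9
```

One hectare of riparian grassland supports at most 0.94 yak for a year; the
sustainable rate is 0.38. On the synthetic landscape the pipeline recovers
the 40% utilization the census generator was asked to produce to within half
a percentage point (the residual is integer-herd rounding), and areas
landing just above 40% are classed unsustainable.

A file-based run (`validate_run_config()` + `run_assessment()`, or the
`inst/scripts/rangecap` command-line wrapper with `simulate` and `assess`
subcommands) writes a CSV report, per-scenario utilization rasters and a
provenance record.

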