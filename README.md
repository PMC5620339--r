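# accesscape

Raster travel-time accessibility modelling of emergency obstetric and
neonatal care (EmONC), for epidemiologists and health-programme planners who
need to know *what fraction of births has good geographic access to
life-saving obstetric care, and where upgrades or transport interventions
would help most*.

## What it computes

Given a land-cover grid, road / river / boat-route polylines, a DEM,
facility coordinates and a gridded live-birth surface, the package:

1. **Builds a combined land-cover friction surface** — rivers are burnt in
   as barriers, then roads (six classes), then boat routes, so road–river
   crossings behave as bridges.
2. **Accumulates least-cost travel time** to the nearest EmONC facility
   with an exact multi-source Dijkstra sweep (C++). Each step between
   adjacent cells *i → j* costs

   ```
   t(i, j) = d/2 · (1/v_i + 1/v_j)        [minutes]
   ```

   where `d` is the centre-to-centre distance and `v` the per-class speed
   from the scenario table. Walking speed is slope-corrected by the Tobler
   hiking model, evaluated in the traveller's direction of motion (toward
   the facility):

   ```
   v_walk(s) = v_flat · exp(−3.5 · |s + 0.05|) / exp(−3.5 · 0.05)
   ```

   Motorized and bicycle speeds are isotropic. Four scenario tables
   (walking / cycling / motorcycle / car; boats at 15 km/h in all four;
   wetlands, rivers and open water impassable) encode the published
   dry-season speeds.
3. **Classifies 30-minute travel-time zones** (0–30, 31–60, 61–90, 91–120,
   >120 min) and 2-hour catchments ("good access" = at or under 2 h), plus
   the all-modes surface (cell-wise minimum) and the mode-combination map.
4. **Aggregates births** per zone, per scenario and per administrative
   council by centre lookup (the birth raster is never resampled), and
   estimates absolute birth counts from demographic parameters.
5. **Ranks facility-upgrade candidates** by the births their 2-hour
   catchment would newly cover, one-shot or greedily.

A seeded synthetic-landscape generator (`simulateRegion`) emulates the
statistical structure of the study region — land-class mix (34% grassland,
8% cropland, 34% forest, 14% water), 800–2,400 m relief, a western lake
with an offshore boat corridor and docks, a sparse classified road network
over ~120 villages, 11 EmONC facilities among 127 sites, births
concentrated in settlements, 8 councils — so the entire pipeline runs and
is tested with no external data.

## Worked example

```r
library(accesscape)

region <- simulateRegion(kigomaLikeDefaults(seed = 1))
res <- runPipeline(region, outDir = "pipeline_out")
round(100 * unlist(res$poor_access_regional), 1)
#>    walking    cycling motorcycle        car  all_modes
#>       94.8       85.5       68.4       80.5       68.0
```

These are the percentages of the region's 83,000 expected live births with
*poor* geographic access (more than 2 hours to the nearest EmONC facility)
under each travel scenario on the seed-1 synthetic region. The ordering —
walking worst, then cycling, then car, then motorcycle, with the all-modes
best case below every single mode — mirrors the published regional
analysis; absolute levels depend on the synthetic network density.
`pipeline_out/` holds the travel-time, zone and catchment grids (ESRI
ASCII), per-scenario coverage CSVs, the mode-combination map and a JSON
summary with a built-in dominance audit.

Upgrade planning:

```r
emonc <- region@facilities[region@facilities$is_emonc, ]
cand  <- region@facilities[!region@facilities$is_emonc, ][1:5, ]
rankUpgradeCandidates(cand, emonc, region@combined, region@dem,
                      defaultSpeedTable("motorcycle"), region@births)
```

A command-line wrapper lives at `inst/cli/accesscape.R`
(`simulate`, `travel-time`, `run` subcommands).

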