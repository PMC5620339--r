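---
title: "Modelling geographic access to emergency obstetric care on raster landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling geographic access to emergency obstetric care on raster landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accesscape)
```

## The model

The package estimates, for every cell of a raster landscape, the minimum
time a woman in labour needs to reach the nearest facility providing
emergency obstetric and neonatal care (EmONC), under a set of travel
scenarios, and then aggregates a gridded live-birth surface over the
resulting travel-time bands. "Good geographic access" is travel time at or
under 2 hours — the conservative window for reaching care for complications
such as obstetric haemorrhage.

### Friction surface and step costs

The landscape is a *combined land-cover raster*: a base grid of six cover
classes (forestland, grassland, cropland, settlement, wetland, other land)
over which river polylines are burnt as an internal barrier class, then six
road classes, then boat routes. Later burns overwrite earlier ones, which
gives road–river crossings implicit bridge semantics; any other order would
sever the road network at every crossing. Two internal codes extend the
thirteen user-facing classes: `river_barrier` (identical in behaviour to
wetland, kept separate for provenance) and `water` (open lake, impassable
except where a boat route is burnt).

Travel accumulates over steps between adjacent cells. A step of length $d$
from cell $i$ to cell $j$ costs

$$ t(i,j) \;=\; \frac{d}{2}\left(\frac{1}{v_i} + \frac{1}{v_j}\right), $$

the harmonic half-cell composition standard in cost-surface analysis: each
cell contributes half the step at its own speed. Speeds come from the
scenario's speed table (below). If either cell is impassable the step is
impossible.

### Anisotropic walking

Walking speed responds to terrain. With slope $s$ (rise over run, positive
uphill, always evaluated in the traveller's direction of motion — toward
the facility), walking speed is modulated by the Tobler hiking factor

$$ m(s) \;=\; \frac{e^{-\alpha\,|s + \beta|}}{e^{-\alpha\beta}},
   \qquad \alpha = 3.5,\; \beta = 0.05 . $$

The factor is exactly 1 on flat ground, peaks at a gentle downhill of
$-\beta$, and decays symmetrically about it. The published analysis states
that Tobler's correction was applied but not how the software anchored it;
two readings are possible, and both are provided. The default
(`normalizeToFlat = TRUE`) treats the per-class table speeds as
flat-terrain speeds that slope modulates — this respects the table's
walking speeds as printed. The alternative (`FALSE`) uses the raw
exponential, whose flat-ground value is $e^{-\alpha\beta} \approx 0.84$; on
uniform terrain the two differ by exactly that constant factor in every
walking time, a property the test suite checks. Motorized speeds need no
directional adjustment, and bicycle speed is *deliberately* isotropic by
default, mirroring a documented limitation of the original analysis
software; `anisotropicBicycle = TRUE` switches slope correction on for
bicycles for sensitivity analysis.

### Scenario speed tables

Four scenarios pair one primary mode with walking (everyone walks off-road)
and boats (15 km/h along boat routes in every scenario, since lakeside
villages may use boats for part of any trip). The packaged per-class speeds
(km/h, dry season):

| class | walking | cycling | motorcycle | car |
|---|---|---|---|---|
| forestland | 1.0 | 1.0 (walk) | 1.0 (walk) | 1.0 (walk) |
| grassland | 1.7 | 7.0 | 7.0 | 1.7 (walk) |
| cropland | 1.7 | 1.7 (walk) | 1.7 (walk) | 1.7 (walk) |
| settlement | 2.5 | 7.0 | 7.0 | 2.5 (walk) |
| other land | 2.5 | 7.0 | 7.0 | 2.5 (walk) |
| boat route | 15.0 | 15.0 | 15.0 | 15.0 |
| major road | 2.5 | 10.0 | 40.2 | 50.0 |
| major road, residential | 2.5 | 10.0 | 26.2 | 30.0 |
| secondary road | 2.5 | 10.0 | 35.2 | 40.0 |
| local road (all vehicles) | 2.5 | 10.0 | 15.0 | 15.0 |
| local road (moto/bike) | 2.5 | 10.0 | 15.0 | 2.5 (walk) |
| local road (walking) | 2.5 | 2.5 | 2.5 | 2.5 |

Wetland, river and open-water cells are impassable in every scenario.
Entries marked "(walk)" are classes where that scenario's vehicle cannot
travel and the table falls back to walking, exactly as the source table is
printed column by column. Tables serialize to YAML
(`writeSpeedTables()` / `readSpeedTables()`) and round-trip exactly, so
speed assumptions — the analysis's main sensitivity — are auditable inputs.

### Accumulation

`accumulateTravelTime()` runs an exact multi-source Dijkstra sweep
(implemented in C++ with a binary heap; no randomness, total-order
tie-break) outward from all facility source cells while costing every edge
for the *inward* traversal, so slopes always refer to travel toward care.
`oracleTravelTime()` is an independent reference with the same contract: it
materializes the explicit weighted directed graph and delegates to
`igraph::distances()`. The two are compared on random mixed-class
landscapes in the test suite at a relative tolerance of 1e-9.

## Tunable parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `breaks` | minutes | 30, 60, 90, 120 | four incremental 30-minute zones up to the 2-hour limit |
| threshold (last break) | minutes | 120 | good access defined as *at or under* 2 h; 120.0 is inside |
| `connectivity` | neighbours | 8 | queen moves; 16 adds knight moves, shrinking the worst-case metric distortion from 8.24% to ~2.8% |
| `ToblerParams` steepness / offset | — | 3.5 / 0.05 | constants of the cited hiking function (not printed in the source analysis); configurable |
| `normalizeToFlat` | — | TRUE | treat table speeds as flat-terrain speeds (see above) |
| snap radius | cells | 10 | facility GPS error is metres; snapping only repairs rasterization artifacts |

Degenerate inputs are errors, not silent defaults: no sources, all sources
on barriers, empty zone breaks, non-increasing breaks, zero total births,
facilities outside the grid, grid mismatches between co-registered layers.
Councils with zero births report `NA`, never 0, to avoid silent bias.

## Numerical and geometric conventions

* **Rasterization rule.** A cell is burnt when its centre lies within half
  a cell size of a polyline, or strictly inside a polygon (centre rule).
  The source analysis does not state its rule; this one is fixed and
  documented for reproducibility, and is verified against an exhaustive
  per-cell geometric test.
* **Grid indexing.** Row 1 is the northern edge; origin is the lower-left
  corner; cell centres at `origin + (index − 0.5) · cellSize`.
* **Corner rule.** A diagonal step is forbidden when both orthogonally
  shared cells are barriers (no squeezing between barrier corners). Knight
  moves (16-connectivity) are forbidden when both cells nearest the move's
  midpoint are barriers.
* **Zone boundaries.** Closed upper bounds: 30.0 min is zone 0–30 and
  120.0 min is good access. Unreachable cells fall in the over-2-hours
  band.
* **Cross-resolution aggregation.** Birth cells are assigned to the zone,
  catchment or council containing their centre; the birth raster is never
  resampled (its producer recommends against it). Totals are conserved
  exactly — every birth cell lands in exactly one zone, with off-grid
  centres counted as over-threshold under a warning.
* **Zone vectorization.** `vectorizeZones()` decomposes each zone into
  axis-aligned rectangles (maximal vertical merges of row runs), conserving
  area exactly and re-rasterizing to the identical zone raster. Both the
  polygon route (fidelity to the original workflow, including its
  acknowledged border error) and direct raster zonal statistics (default,
  exact) are available.
* **Unreachable cells** carry `NA` in memory and the nodata value on disk,
  never a numeric sentinel.

## The synthetic landscape generator

`simulateRegion()` produces a fully deterministic (single seeded PRNG,
fixed operation order) landscape with the statistical structure the
analysis assumes:

* **Land cover** — a correlated random field (iterated box blur of white
  noise; correlation radius configurable) thresholded *by rank*, so
  realized class fractions hit their targets to within a cell: 34%
  grassland, 8% cropland, 34% forest, 14% water, the remainder split among
  settlement, other land and wetland. Water forms a western lake with a
  noisy shoreline; wetlands occupy the lowest-elevation land, mimicking
  drainage.
* **Relief** — a smooth field blended with a north/south highland profile,
  scaled exactly to 800–2,400 m; lake cells sit at the base elevation.
* **Network** — villages are sampled in settlement patches by greedy
  farthest-point sampling; roads are the minimum spanning tree over
  villages plus extra short edges up to a target density of 0.05 km/km²,
  with edge weights penalized for crossing water; edges are classed
  major/secondary/local by betweenness rank, local edges split into car-,
  motorcycle/bicycle- and walking-only. Major-road cells crossing
  settlement cover are recoded as the residential major-road class. Rivers
  descend from highland sources by steepest descent (elevation
  non-increasing by construction). The boat route parallels the shoreline
  60 m offshore, with dock spurs connecting shoreline villages.
* **Population** — 11 EmONC facilities (a CEmONC-heavy care-level mix with
  partially functional CEmONC and BEmONC sites) among 127 candidate sites;
  83,000 expected births distributed over non-water cells with a
   multiplicative settlement weight of 50, aggregated to a 100 m birth
  lattice and summing exactly to the configured total; 8 councils as a
  raster Voronoi partition around spread village seeds.

### Why the default region is 1500 × 1500 cells of 140 m

The defining structural feature of the study system is the *ratio of
facility spacing to per-mode 2-hour travel range*: walking reaches 2–5 km,
bicycles roughly 14–20 km, motor vehicles up to 80–100 km along roads,
while the 11 EmONC facilities serve a region of ~45,000 km² (spacing
~60 km). A small grid at the nominal 30 m resolution (a few hundred cells,
i.e. ~10 km of extent) puts every cell within bicycle range of a facility
and collapses the scenario gradient entirely. The default therefore keeps
the *area* (210 × 210 km ≈ 44,100 km²) and coarsens the cell to 140 m,
preserving the scale relations at a desk-scale cell count (2.25 M cells;
the full four-scenario pipeline runs in about a minute on one CPU). The
cost is a worse road-width artifact — a road burns the full 140 m cell —
which biases access around roads upward; the same artifact exists at 30 m
and is inherent to rasterized road networks.

### What the generator does and does not emulate

It reproduces class fractions, patch contiguity, relief range, a sparse
classified road network over villages, an offshore boat corridor with
docks, settlement-concentrated births, and facility clustering in the
largest villages. It does **not** calibrate against real road topologies,
real population gradients (e.g. the strong lakeside concentration of the
actual region), seasonal passability, or the data-quality artifacts of
crowdsourced road maps. Consequently, passing tests demonstrate the
*correctness of the machinery* (exact shortest paths, conservation,
dominance orderings, determinism) and the *qualitative* behaviour of the
analysis — poor access shrinking strictly along the
walking → cycling → motorcycle chain, all-modes at least as good as every
single mode — but the absolute poor-access percentages of a synthetic
region are properties of the generator, not estimates for any real region.

## Known limitations

* One idealized journey per scenario: travellers use the primary mode
  wherever the table allows and walk elsewhere; no mode switching costs,
  waiting times, or availability constraints.
* Dry-season speeds only; no rainy-season tables, traffic or stochastic
  speeds.
* Exact replication of the original software's numeric output is not
  claimed: its connectivity, edge composition and Tobler anchoring are
  undocumented; this package documents its own choices and verifies them
  against an independent oracle instead.
* Travel times only; path extraction/back-tracing is out of scope, as the
  coverage analysis needs no routes.
* No uncertainty propagation for the birth surface.
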