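---
title: "Modelling drive-time access to acute stroke care: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drive-time access to acute stroke care: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intravenous thrombolysis for acute ischaemic stroke is most effective
within the first hour after symptom onset, yet certified stroke units are
unevenly distributed: many rural areas cannot reach one within a
clinically useful drive time. Almost every acute-care hospital, however,
operates a CT scanner. A *hub-and-spoke* (drip-and-ship) pathway — initial
imaging and thrombolysis at the nearest CT-equipped hospital under
telemedical supervision, followed by transfer to a specialised unit — can
shorten time to imaging wherever the nearest CT hospital is substantially
closer than the nearest stroke unit.

`strokeaccess` quantifies that trade-off on a gridded landscape. For every
1-km cell it computes minutes by road to the nearest facility of each care
tier, derives drive-time isochrones, masks a population raster to produce
coverage tables, and classifies each cell by the time a hub-and-spoke
pathway would save over direct transfer, under driving-speed and
in-hospital-delay scenarios. Results are aggregated nationally, by
urban/rural settlement class, and within states and counties.

## The model

### Facility tiers

A raw facility table is filtered into nested analysis sets:

* **CT-equipped hospitals** — at least 3 CT procedures in the reporting
  year (after deduplication by normalised name and coordinates rounded to
  100 m);
* **stroke-ready hospitals** — at least 100 complex acute-stroke
  procedures per year *or* stroke-unit certification;
* **certified stroke units**, subdivided into supra-regional, regional and
  telemedicine-supported regional units (the latter a subclass of
  regional), plus thrombectomy centres.

Certification implies stroke-readiness, and a certified unit without CT is
clinically implausible, so nesting (certified &sube; stroke-ready &sube;
CT-equipped) is enforced: violations are coerced with a warning by
default, or rejected with `on_nesting_violation = "fail"`.

### Travel-time fields and isochrones

Routing is multi-source Dijkstra over an explicit road graph with per-edge
time `length / (speed x multiplier)`. Each grid cell receives the time of
a straight-line access leg from its centre to the nearest network node
(default 30 km/h, configurable) plus that node's shortest-path time to the
nearest source; equidistant nearest nodes are broken by lowest node id so
fields are deterministic. Times are stored exactly — the 60-minute horizon
is a *classification* constant, applied only when categories are formed,
so there is a single source of truth for "within 60 min".

Isochrones at 5-minute steps up to 60 minutes are unions of the closed
cells with time &le; t, dissolved into rectangle multipolygons. Cell-union
geometry (rather than smoothed contours) makes polygon masking and direct
grid thresholding agree *exactly*: the population inside an isochrone is
precisely the population of its cells. Externally produced isochrone
polygons can be ingested from GeoJSON instead; they are rasterised by the
cell-centre rule and repaired by cumulative union if their nesting is
violated.

Speed scenarios are exact algebra: multiplying every speed (edges and
access leg) by *m* divides every travel time by *m*, so the 0.8x and 1.2x
scenarios are derived from the baseline field and equal recomputation from
scratch to floating precision.

### Benefit classification

For each cell, with `t_ct` and `t_target` the minutes to the nearest
CT-equipped hospital and nearest comparison facility (certified stroke
unit or stroke-ready hospital), and `p` the in-hospital delay penalty:

* target unreachable (> 60 min) and CT unreachable → **neither reachable**;
* target unreachable, CT reachable → **only CT reachable**;
* otherwise `saving = t_target − (t_ct + p)`: below 10 min →
  **irrelevant**, [10, 20) → **low**, [20, 30) → **medium**, ≥ 30 →
  **high**.

Boundaries are half-open with "high" starting at a saving of exactly
30 min, and "within 60 min" is inclusive (a facility at exactly 60.0 min
counts as reachable). The penalty is added to the CT time after routing
and *before* classification, but by default does **not** enter the 60-min
reachability test, so the only-CT and neither categories are invariant
across penalty scenarios; the stricter reading (a CT hospital at 55 min
with a +10 min penalty no longer counts as reachable) is available via
`penalty_affects_reachability = TRUE`. Both choices are defensible; the
default reflects how penalty scenarios are conventionally tabulated, and
the toggle keeps the alternative testable.

The canonical scenario set is: multiplier 1.0/1.2/0.8 at penalty 0, and
penalties 10/20/30 min at multiplier 1.0. Penalty scenarios reuse the
baseline fields (the penalty is a classification shift, not a routing
change), which also makes penalty monotonicity exact: the beneficiary
population (saving ≥ 10 min) is non-increasing in the penalty.

### Denominators and rounding

Published coverage and benefit tables mix percentage conventions, so the
convention is an explicit, carried column rather than an assumption:
`fixed_national` (a supplied national figure, e.g. 83,420,000),
`raster_total` (the population raster sum), and `category_sum` (the sum
over the six benefit categories; identical to the raster total on a full
partition, but distinct when a fixed national figure is used elsewhere).
Percentages are rounded half-up to one decimal for display only; raw
counts are always retained.

### Urbanisation and regions

Settlement codes follow the degree-of-urbanisation convention: 30, 23,
22, 21 are urban; 13, 12, 11 rural; 10 (water) and anything else "other".
Area shares of a mask are reported under two conventions — composition of
the mask, and coverage of each class's total area — because both styles
are in common use and they answer different questions.

States and counties are nested Voronoi partitions assigned by cell
centre: every cell belongs to exactly one county and one state, so county
populations and areas sum to their state's, and states to the national
total, exactly. Regional tables recompute coverage and benefit per region
with the region's own raster total as denominator.

## The synthetic-region generator

The generator emulates the statistical structure of the real inputs so
the pipeline is testable end to end without national datasets:

* **Population raster** — a mixture of Gaussian urban clusters (scales
  drawn between 2% and 8% of the extent, Zipf-like weights so a few
  centres dominate) over a uniform rural floor carrying 15% of the mass,
  rescaled to the requested total exactly. Density, not demographics, is
  what the analysis consumes.
* **Settlement raster** — codes assigned by density band at boundaries
  5 / 50 / 150 / 300 / 600 / 1500 persons/km², loosely modelled on
  degree-of-urbanisation cut-offs; an optional water mask emits code 10.
* **Road network** — a jittered lattice of 50 km/h local roads plus
  100 km/h corridors along the minimum spanning tree of the urban
  centres. This is deliberately coarser than a real national road
  network; absolute travel times are slower than, e.g., German reality,
  and are not calibrated to it.
* **Facilities** — sites sampled proportional to population and snapped
  to the road network, with nested tiers (the most populous sites get the
  specialised tiers, telemedicine-supported units preferentially in the
  least populous certified sites, thrombectomy centres = supra-regional
  units) and tier-conditioned procedure counts chosen only to exercise
  the registry filters. A configurable decoy fraction adds sub-threshold
  rows.
* **Admin regions** — nested Voronoi partitions of random seed points.

Default dimensions are a 250 x 250 km region at 1-km resolution with
15 million inhabitants (about 240 persons/km², a central-European
density), 8 urban centres, a 5-km road lattice, and 260/85/62 facilities
per tier — roughly the facility-per-inhabitant ratios of a large European
country. One integer seed drives every sub-generator through fixed child
seeds, so regions reproduce bit-identically.

What passing tests on synthetic regions do *not* show: agreement with any
real country's coverage numbers. Real road networks are denser and
faster, real population rasters have sharper structure, and real facility
registries have data-quality quirks beyond duplicated rows. The synthetic
results validate the machinery (conservation, monotonicity, oracle
equivalence, scaling laws), not national estimates.

## Numerical choices

* Flat projected plane in metres, lower-left origin, half-open 1-km
  cells; all masking by cell centre. This avoids geodesy entirely and
  makes every aggregation exactly conservative.
* Unreachable cells hold `+Inf`, written as nodata in ASCII grids.
* Ties (nearest node, nearest Voronoi seed) break to the lowest id.
* `Inf` arithmetic is used as-is in classification: `Inf + p = Inf`,
  comparisons behave correctly at the horizon.
* Dense uniform test networks use a 16-direction lattice (axis, diagonal
  and knight-move edges) whose shortest-path unit ball covers ~97% of the
  Euclidean disc, so isochrone areas can be checked against the
  closed-form &pi;(vt/60)² within discretisation tolerance.
* Degenerate inputs are defined, not errors, where a meaning exists: zero
  total population yields an all-zero raster; zero urban centres a
  uniform raster; an all-unreachable field yields empty isochrones with a
  warning; empty source sets are errors.

## Problem sizes

The test suite runs on regions of 20–60 km with 1–2 km cells and networks
of 60–2,400 nodes; the acceptance script runs the full default region
(62,500 cells, ~2,600 nodes) in about a minute. Both scale linearly in
cells x nodes for the access-leg assignment and in the usual Dijkstra
bounds for routing.

## Known limitations

* No one-way streets, turn restrictions, or time-of-day congestion; the
  speed multiplier is uniform.
* The straight-line access leg is a simplification of off-network travel;
  its speed is configurable but constant.
* Isochrone polygons are cell unions, not road-following contours; they
  are exact for population accounting but coarser cartographically.
* The generator does not emulate geocoding error, demographic structure,
  or cross-border spillover (the synthetic extent has no neighbours; with
  real data the choice of clipping isochrones at a border changes
  denominators and should be made explicitly).
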