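---
title: "Measuring road-network accessibility of antivenom-stocked hospitals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring road-network accessibility of antivenom-stocked hospitals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gauss2sfca)
```

## The problem

Antivenom is the only effective treatment for snakebite envenoming, and the
time to reach a stocked hospital drives outcomes (the WHO benchmark for
"timely" is one hour). Stocking is sparse and type-specific: a province may
have only a couple of dozen hospitals holding any antivenom, split unevenly
across the four monovalent types (*Agkistrodon halys*, *Naja*,
*Bungarus multicinctus*, *Agkistrodon acutus*), with only a handful
stocking all four. Two questions follow: *how long does each populated
place take to reach the nearest stocked hospital, per type?* and *how much
supply is effectively available per person once distance decay and
competition from everyone else in a hospital's catchment are accounted
for?* This package answers both on a classified road network.

## Model and assumptions

### Demand surface

Population comes as a ~100 m gridded raster whose per-unit sums typically
disagree with the authoritative census. `correct_raster()` applies the
standard linear fix: for each administrative unit,
`factor = census_pop / sum(raster cells in unit)`, every cell multiplied by
its unit's factor, so post-correction unit sums equal the census exactly.
Raster cells are assigned to units (and later to fishnet cells) **by their
center point** — each cell counted exactly once. This is what makes both
conservation statements exact identities rather than approximations; the
alternative, area-weighted splitting of boundary cells, is not described by
the provincial methodology this follows and would break exactness for no
measurable gain at 100 m resolution.

`build_fishnet()` tiles the study extent with 2 km squares from the
lower-left corner; partial edge cells are kept, and a cell's centroid (the
geometric center of the nominal square) approximates its population center
of mass. Each centroid becomes a demand point carrying the corrected
population inside the cell. Reported band "areas" are nominal
`count × 4 km²`, matching the provincial report's arithmetic even for
boundary cells.

Degenerate cases: a unit with positive census but zero raster population
gets the census spread uniformly over its cells (deleting population
silently would bias demand); cells inside no unit are left uncorrected and
counted in a warning. Zero-population fishnet cells are **retained** by
default — they contribute nothing to any catchment sum, so results are
unchanged, but keeping them makes the generated-vs-routed point counts
transparent (the motivating survey reports 8,866 generated centroids but
8,707/8,708 routed without stating its exclusion rule, so this package logs
both counts rather than guessing the rule; `drop_empty = TRUE` drops them).

### Travel costs

`build_graph()` turns classified polylines into an undirected graph: nodes
at segment vertices (coordinates merged at 1e-6 m), edge time
`length_km / speed_kmh × 60` minutes with the nine-class speed table
(highway 100, expressway 80, arterial 60, feeder/other/internal 20, rural
30, bicycle 15, pedestrian 5 km/h). Known limitations, inherited from the
underlying model: no one-way streets, turn penalties, traffic, or
multi-modal travel.

Demand points and facilities snap to the **nearest node** (ties to the
lower node id; default limit 5 km, beyond which a point is flagged
unreachable). Snapping to the nearest point on an edge would be slightly
more accurate but complicates topology; the synthetic generator places
facilities on nodes precisely so fixture tests are exact, and 2 km demand
centroids on a ≤5 km lattice snap within half a cell. Off-network access
time from the true location to the snapped node is ignored (network-only
model). Shortest paths are Dijkstra on the time weight (via igraph); the
kilometre figure is measured **along the time-optimal path**, since the
source methodology reports "shortest distance/time" as one quantity.

### Gaussian 2SFCA

With catchment threshold $d_0$ and cost $d$ in the same unit,

$$G(d) = \frac{e^{-\frac12 (d/d_0)^2} - e^{-\frac12}}{1 - e^{-\frac12}}
\quad (d < d_0), \qquad G(d) = 0 \ (d \ge d_0).$$

Step 1 (per facility $j$ with supply $S_j$):
$R_j = S_j / \sum_{k:\, d_{jk} \le d_0} G(d_{jk}) D_k$.
Step 2 (per demand point $i$):
$A_i = \sum_{j:\, d_{ij} \le d_0} G(d_{ij}) R_j$,
run once with beds and once with health technicians as $S_j$. $A_i$ is in
supply units per person (`*_per_1000` columns for reporting).

Design notes:

- **Kernel form.** The source's kernel formula is typographically garbled;
  the form above is the standard Gaussian-2SFCA kernel and the unique
  reading that decays from $G(0)=1$ to $G(d_0)=0$, consistent with the
  stated "law of distance attenuation".
- **Boundary.** One equation writes $d < d_0$, the other $d \le d_0$;
  since $G(d_0) = 0$ exactly, both sums are implemented with $\le$ and the
  kernel returns 0 at the boundary — the choice is immaterial.
- **Threshold.** Default `decay_params(d0 = 40, cost_basis = "distance")`:
  the methodology states a 40 km network-distance service radius
  explicitly. It also equates this with a "15-minute drive time", which is
  inconsistent at any single speed (40 km at even 100 km/h is 24 min);
  `cost_basis = "time"` with a minute threshold is supported so users can
  take the other reading, and outputs should be labelled with the basis
  used.
- **Empty catchments.** A facility whose catchment holds zero weighted
  demand has unallocatable supply: $R_j$ is flagged and set to 0, and the
  conservation identity is asserted over non-empty catchments only.
- **Symmetry.** $d_{jk} = d_{kj}$ on the undirected network, so one OD
  matrix serves both steps.

The load-bearing identity — used as an acceptance property — follows by
exchanging the two sums:
$\sum_i D_i A_i = \sum_j R_j \sum_i G(d_{ij}) D_i = \sum_j S_j$,
exactly, whenever every catchment is non-empty. It holds to 1e-9 relative
in floating point at any problem size, so it detects indexing, masking and
weighting bugs anywhere in the chain.

### Band report

Nearest-facility times per antivenom subset (each of the four types, the
all-four stockers, and the pooled set) are classified into
$[0,30], (30,60], (60,90], (90,120], (120,\infty)$ minutes — boundaries
belong to the lower band, so 30.0 min is "≤30". Rows carry count,
proportion (1 decimal, half-up), nominal area `count × 4 km²`, and band
population in persons plus a $10^4$-person display column: the provincial
table's header says "thousands", but its own headline one-hour figures
(e.g. 85.6 + background → 856,000 people) only reconcile at $10^4$, so the
package stores persons and documents the mislabel. The `>1 h` roll-up sums
bands strictly above a boundary threshold.

## The synthetic province

`generate_province()` emulates the four proprietary inputs with a stated,
fixed world — parameters were chosen once to mirror the motivating survey
where it states values, and are not tuned to test outcomes:

- **Extent** 50 km × 40 km (planar metric coordinates; the real analysis
  projects to Transverse Mercator before measuring, so planar geometry
  preserves the math while dropping geodesy) → 500 fishnet cells,
  matching the "~500 demand points" working size.
- **Roads**: a connected lattice (5 km spacing) with expressway, arterial
  and rural classes in a deterministic pattern, so three distinct speeds
  are exercised and every intersection is a shared node by construction.
- **Population**: lognormal per 100 m cell (heavy-tailed settlement
  structure, nonnegative, integer-rounded), ~1M persons total — a
  plausible provincial population at this cell density.
- **Census distortion**: per-unit factors drawn from [0.8, 1.25] and
  recorded, so the correction step has real work to do and tests can
  recompute the factors independently by zonal summation.
- **Facilities**: 25, placed on road nodes (so fixture travel times are
  exact, not snapping-confounded), lognormal beds with technicians ≈
  1.0–1.6× beds, and stocking drawn with the survey's per-type shares
  (21/25, 14/25, 11/25, 11/25); facility 1 always stocks all four so every
  subset, including all-types, is non-empty.

What the generator does **not** emulate: island topology, dasymetric
(land-cover-driven) population placement, realistic road hierarchies or
network detours, seasonal/traffic variation. A green test on synthetic
data therefore establishes the *computational* correctness of each stage
(conservation, oracle equivalence, determinism) — not that real-province
results would be numerically similar.

`known_answer_scenario()` is the hand-checkable fixture: one facility
(supply 10) on a straight arterial, two populated demand cells at network
distances 0 and 20 km with 100 persons each, $d_0 = 40$ km. Then
$G(20) = (e^{-0.125} - e^{-0.5})/(1 - e^{-0.5}) = 0.7013666$,
$R = 10/(100 + 100G) = 0.0587763$, $A(0) = R$, $A(20\,\text{km}) = GR =
0.0412237$, and $\sum_i D_i A_i = 10$.

## Numerical choices

- Node merge tolerance 1e-6 m; geometry round-trips asserted at the same
  tolerance.
- Proportions and $10^4$-person displays round half-up (base R's
  round-half-even would print 0.5-boundary cells differently than the
  reference tables).
- Snap ties break to the lower node id; nearest-facility ties to the lower
  facility id (numeric order when ids are numeric) — deterministic
  reruns.
- Unreachable anything is `Inf` internally, `NA` in exports, excluded from
  band denominators, and listed via the generated/routed counts.
- Conservation and oracle-equivalence tolerances are 1e-9 relative;
  census-correction conservation 1e-6 relative (one multiply and large
  sums).

## I/O formats

This build is text-only: GeoJSON (RFC 7946) for roads, admin polygons and
scored demand points; ESRI ASCII grid (`.asc`) for rasters — the same
single-band grid model as GeoTIFF in a plain-text container, chosen
because no binary-raster reader is assumed present; CSV for facilities,
census totals, OD matrices and band summaries. Inputs must share one
projected metric coordinate system; the package refuses to reproject
(a documented pre-step for real data). Unknown road classes are a hard
error with counts, translatable via `class_map` — silently dropping roads
would bias every travel time downstream.

## Known limitations

- Undirected network, free-flow class speeds, no congestion: travel times
  are optimistic, uniformly so across the province.
- Nearest-node snapping adds up to half a lattice spacing of unmodelled
  off-network distance (zero in all shipped fixtures).
- The published band table is reproduced by arithmetic, not by rebuilding
  the province: the real road, stocking and yearbook supply inputs are not
  redistributable, so end-to-end numeric reproduction of the survey's map
  is out of reach by design. Its internal inconsistencies (the *Naja*
  one-hour headline vs. its own table; a 9.3% vs 9.25% rounding; a 54 vs
  84 km² typo) are documented where relevant and excluded from assertions.
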