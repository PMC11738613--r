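# gauss2sfca

Road-network spatial accessibility of scarce hospital resources, built
around the snakebite-antivenom use case: which parts of a province can
reach an antivenom-stocked hospital quickly, and how much supply (beds,
health technicians) is effectively available per person once distance and
competing demand are accounted for.

Snakebite envenoming is only treatable with antivenom, and outcomes hinge
on reaching a stocked hospital fast — the WHO benchmark is one hour. Few
hospitals stock antivenom, each of the four monovalent types (for
*Agkistrodon halys*, *Naja*, *Bungarus multicinctus* and *Agkistrodon
acutus* bites) is stocked by a different subset, and supply must be shared
with everyone else inside a hospital's catchment. This package implements
the full measurement pipeline for that problem, usable with real GIS
layers or with a built-in synthetic province.

## The method

1. **Demand surface.** A 100 m population raster is linearly corrected so
   each administrative unit's raster sum matches its census total
   (factor = census / raster sum, applied per cell). A 2 km fishnet tiles
   the study area; each cell centroid becomes a demand point carrying the
   corrected population inside the cell (D_k).
2. **Travel costs.** The classified road network becomes an undirected
   graph (intersections = nodes, segments = edges) with class speeds
   highway 100, expressway 80, arterial 60, feeder/other/internal 20,
   rural 30, bicycle 15, pedestrian 5 km/h. Dijkstra shortest paths by
   travel time give the origin–destination cost matrix (minutes, and km
   along the time-optimal path); the nearest stocked facility per demand
   point feeds the travel-time band report (≤30, 30–60, 60–90, 90–120,
   >120 min) per antivenom type.
3. **Gaussian 2SFCA.** With catchment threshold d0 (default 40 km network
   distance) and the truncated Gaussian kernel

       G(d) = (exp(-(d/d0)^2 / 2) - exp(-1/2)) / (1 - exp(-1/2)),  d < d0
       G(d) = 0,                                                   d >= d0

   step 1 computes each facility's supply-to-weighted-demand ratio
   R_j = S_j / Σ_k G(d_jk) D_k over demand within d0, and step 2 sums
   A_i = Σ_j G(d_ij) R_j over facilities within d0. A_i is supply per
   person (beds or technicians; ×1000 columns for reporting); higher is
   better, and Σ_i D_i A_i = Σ_j S_j exactly.

## Worked example

```r
library(gauss2sfca)

b <- generate_province(province_spec(seed = 7))   # synthetic province
b
#> <province_bundle> 178 road segments, 6 admin units, 25 facilities, 998417 persons

res <- run_pipeline(b)          # correction -> fishnet -> OD -> bands -> 2SFCA
res$bands
#>        band n_points proportion_pct area_km2 population_persons population_1e4
#> 1      <=30      500            100     2000            1127801          112.8
#> 2  30<m<=60        0              0        0                  0            0.0
#> ...

head(res$points[order(-res$points$A_beds), c("population", "travel_min", "band", "A_beds")], 3)
#>     population travel_min band      A_beds
#> 237   2695.084       3.75 <=30 0.005928775
```

Every demand point in this dense toy lattice is within 30 minutes of a
stocked hospital; `A_beds = 0.0059` means ~5.9 beds effectively available
per 1000 people at that point. The conservation identity holds exactly:

```r
sum(res$demand$population * res$scores$A_beds)   # 5130
sum(b$facilities$beds)                           # 5130
```

The report operations also run on the published provincial band table
(the printed counts/populations are inputs, shipped in
`reference_band_table()`): the population more than an hour from an
*Agkistrodon halys*-stocked hospital is

```r
over_threshold_population(reference_band_summary("hyalys")$summary, 60)
#> [1] 856000
```

Real inputs go through `read_roads()`, `read_pop_raster()`,
`read_admin_units()`, `read_facilities()` (or `read_province()` on a
directory), then `run_pipeline()` and `write_outputs()`. A command-line
wrapper with `--roads --raster --admin --census --facilities --out` flags
is in `inst/cli/run_accessibility.R`.

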