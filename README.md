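# spaccess

Network-based walking accessibility of urban health services, with the
point-pattern and autocorrelation statistics used in spatial-justice studies
of deprived neighbourhoods.

`spaccess` is for analysts who have (or want to simulate) three things — a
street network, census blocks with populations by sex and age band, and
health-facility locations — and who want to answer: *which share of each
population stratum can walk to a facility within the service standard, and is
deprivation spatially clustered while facilities are not?*

The package implements:

* **Average nearest neighbour (ANN)** ratio against the CSR null:
  ANN = D̄₀/D̄ₑ with D̄ₑ = 0.5/√(n/A), SE = 0.26136/√(n²/A) and
  Z = (D̄₀ − D̄ₑ)/SE.
* **Global Moran's I** — I = (n/S₀)·ΣᵢΣⱼ wᵢⱼ zᵢ zⱼ / Σᵢ zᵢ², E[I] = −1/(n−1),
  with the normality-assumption variance and optional permutation inference;
  weights schemes: inverse distance, distance band, k-nearest, rook.
* **Quartic-kernel density surfaces** with the standard-distance bandwidth
  rule h = 0.9·min(SD, √(1/ln 2)·Dm)·n^(−0.2).
* **Walking service areas**: facilities snapped to the street graph,
  single-source shortest paths (default 1 m/s, 750 m radius = 12.5 min
  budget) with partial-edge coverage, buffered into coverage footprints, and
  overlaid on blocks (areal split or centroid rule) to tabulate access /
  no-access counts and percentages per sex × age stratum.
* **A composite deprivation index** (z-standardised indicators, direction
  flags, weighted mean, tercile classes lower/middle/upper).
* **A synthetic-city generator** (jittered-grid streets, log-normal
  population with exact integer conservation, SAR-clustered deprivation
  field, CSR/clustered/custom facility patterns) so the whole pipeline runs
  and is tested without any external GIS data.

All geometry is planar metres; GeoJSON/CSV/YAML are the interchange formats.

## Worked example

```r
library(spaccess)

city <- generate_city(city_config(seed = 1, grid_nx = 20, grid_ny = 20,
  block_size = 150, n_facilities = 25, pop_total = 120000,
  deprivation_rho = 0.8))

nearest_neighbor_stat(cbind(city$facilities$x, city$facilities$y))
#> Average nearest neighbour: ANN = 1.4030 (z = 3.855, p = 0.0001157)
#>   d_obs = 374.127 m, d_exp = 266.659 m, n = 25, A = 7.111e+06 m^2 (min_enclosing_rect)

pov <- composite_score(city$blocks, default_indicator_specs())
w   <- build_weights(block_centroids(city$blocks), "inverse_distance")
morans_i(class_to_value(pov, "ordinal"), w)
#> Global Moran's I = 0.4701 (E[I] = -0.0025, z = 11.517, p = 1.078e-30)

wm  <- walk_model()           # 1 m/s, 750 m -> 12.5 min
sas <- lapply(seq_len(nrow(city$facilities)), function(i)
  service_area(city$roads,
               snap_facility(city$roads, city$facilities[i, , drop = FALSE]), wm))
cov <- union_service_areas(sas)
tab <- tabulate_access(population_with_access(city$blocks, cov),
                       city$blocks, year = 2016)
tab[tab$sex == "total" & tab$age == "total", ]
#>    year   sex   age access_n no_access_n total_n access_pct no_access_pct
#> 15 2016 total total   104406       15594  120000      87.01            13
```

Reading: the 25 facilities are *dispersed* relative to CSR (ANN 1.40,
z 3.86), deprivation is strongly *clustered* (I 0.47, z 11.5), and 13% of
the 120 000 residents live outside a 12.5-minute walk of every facility.
Counts conserve exactly (access + no-access = total per stratum); percentages
are half-up rounded to two decimals.

A full multi-wave study (nested facility waves 29/33/78, per-wave ANN, Moran,
KDE summaries and access tables) runs through a single configuration:

```r
report <- run_pipeline(demo_config())
write_report(report, "report/")
```

or from the shell via the thin CLI:

```sh
Rscript inst/cli/spaccess.R run --config inst/extdata/demo_study.yaml --out report/
```

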