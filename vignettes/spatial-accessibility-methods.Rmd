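---
title: "Methods: network walking access, pattern statistics, and the synthetic city"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network walking access, pattern statistics, and the synthetic city}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaccess)
```

# The problem

`spaccess` asks a spatial-justice question about a city: can its residents —
stratified by sex and by age band (0–14, 15–64, 65+) — reach a health centre
on foot within a reasonable time, and is the answer worse in deprived
neighbourhoods? The package implements the full analysis chain: point-pattern
statistics of facility locations, spatial autocorrelation of a block-level
deprivation classification, kernel density surfaces, and network-based
walking-time service areas overlaid on census blocks to produce access /
no-access tabulations per stratum and census wave.

Because municipal GIS and census microdata are rarely redistributable, the
package also ships a synthetic-city generator whose outputs carry the
statistical structure such studies report — clustered poverty, randomly
patterned facilities, facility density decoupled from population density — so
that every stage is testable end to end without external data.

All geometry is planar metres (a projected CRS). Readers reject inputs whose
coordinates all fit longitude/latitude ranges rather than reprojecting:
projection is the user's job, and silently treating degrees as metres would
corrupt every distance downstream. Genuinely small planar test extents can
opt out via `assume_planar`.

# Point patterns: the average nearest neighbour ratio

For `n` points in an area `A`, with `d_i` the distance from point `i` to its
nearest other point,

$$\bar D_O = \frac{\sum_i d_i}{n}, \qquad
  \bar D_E = \frac{0.5}{\sqrt{n/A}}, \qquad
  \mathrm{ANN} = \frac{\bar D_O}{\bar D_E},$$

$$Z = \frac{\bar D_O - \bar D_E}{SE}, \qquad
  SE = \frac{0.26136}{\sqrt{n^2/A}}.$$

ANN < 1 indicates clustering, ANN ≈ 1 a random (CSR) pattern, ANN > 1
dispersion. When `A` is not supplied it defaults to the axis-aligned minimum
enclosing rectangle of the points — deterministic, and the conventional
implementation choice; a rotating-calipers rectangle would be smaller but is
not what the standard desktop tools compute. Coincident points contribute
`d_i = 0`; collinear point sets have a degenerate rectangle and require an
explicit area.

**Known limitation — boundary bias.** $\bar D_E$ and $SE$ are the
*unbounded-plane* CSR moments. In a bounded window, points near the boundary
lack neighbours beyond it, which inflates $\bar D_O$: the classical boundary
correction adds a term proportional to $P/n$ (perimeter $P$), shifting the
z-score upward by roughly $0.197\,P/\sqrt{A}$ — about $+0.8$ for any square
window, independent of `n`. We deliberately implement the uncorrected
formulas, because they are what the statistic conventionally means in this
analysis tradition; the consequence, which our own simulations quantify, is
that the nominal 95% acceptance band of `|z| < 1.96` under CSR actually
captures roughly 80–85% of realisations, while the ANN *ratio* itself stays
within about 1–2% of 1. Users comparing z-scores to ±1.96 on bounded windows
should be aware the test leans toward "dispersed".

# Spatial autocorrelation: global Moran's I

With attribute deviations $z_i = x_i - \bar x$ and spatial weights $w_{ij}$
(sum $S_0$),

$$I = \frac{n}{S_0}\,
      \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2},
  \qquad E[I] = \frac{-1}{n-1}.$$

`I > E[I]` indicates clustering of similar values, `I < E[I]` dispersion.
The variance under the normality assumption uses the standard moments

$$E[I^2] = \frac{n^2 S_1 - n S_2 + 3 S_0^2}{(n^2-1)\,S_0^2},\qquad
  S_1 = \tfrac12 \sum_{i,j}(w_{ij}+w_{ji})^2,\qquad
  S_2 = \sum_i \Bigl(\sum_j w_{ij} + \sum_j w_{ji}\Bigr)^2,$$

giving $V[I] = E[I^2]-E[I]^2$ and $Z_I = (I - E[I])/\sqrt{V[I]}$. Because the
normality assumption is exactly that — an assumption — `morans_i()` also
offers permutation inference: the attribute is randomly relabelled across
features `n_perm` times under a fixed seed and a two-sided pseudo p-value
$2\min(p_{\ge}, p_{\le})$ with the add-one correction is reported.

**Weights.** The weights conceptualization is a genuinely open choice in this
kind of study, and published analyses frequently omit it. We default to
inverse Euclidean distance with a cutoff equal to the maximum
nearest-neighbour distance (so no feature is isolated) and no row
standardization — the common desktop default — and expose binary distance
bands, k-nearest-neighbour, and rook (shared-boundary) contiguity, each with
optional row standardization. Because the choice materially changes `I`,
reported Moran values are only comparable under the same weights; the
package treats published Moran values from unstated weights as
non-reproducible and does not target them.

# Kernel density

The surface sums a quartic (biweight) kernel per point,

$$f(p) = \sum_k w_k \,\frac{3}{\pi h^2}\Bigl(1 - \frac{d_k(p)^2}{h^2}\Bigr)^2
  \quad (d_k < h),$$

which integrates to the total weight and is exactly zero beyond `h` of every
point (compact support). The default bandwidth follows the standard-distance
rule

$$h = 0.9\,\min\!\bigl(SD,\ \sqrt{1/\ln 2}\; D_m\bigr)\, n^{-0.2},$$

where `SD` is the (weighted) standard distance of the points about their mean
centre, `D_m` the (weighted) median distance to that centre, and `n` the
total weight. The $\sqrt{1/\ln 2}$ factor is our reading of the commonly
garbled typography of this rule; it matches the rule's reference
implementation and gives the hand-check `SD = 100, D_m = 50, n = 100` →
`h ≈ 21.52`. Mass conservation holds to better than 1% once the cell size is
at most `h/10`; the test suite and acceptance script verify both properties
numerically.

# The walking-access model

* **Walking model.** Speed defaults to 1 m/s — the midpoint of the 0.75–1.25
  m/s range used in transport engineering — and the service radius to 750 m,
  so the time budget is `750 s = 12.5 min` of walking.
* **Snapping.** Each facility snaps to the foot of the perpendicular on its
  nearest edge; ties break to the lowest edge id. Facilities farther than
  `max_tol` (default 200 m) from any street are an error, never silently
  dropped.
* **Service area.** Single-source Dijkstra (via igraph) from the snapped
  position with edge cost `length/speed`. Edges are covered *partially*: from
  each end reached at time `t`, coverage extends `(cutoff − t)·speed` metres
  into the edge, and the snapped edge is additionally covered directly from
  the snap point. This is what makes the isochrone boundary fall mid-edge
  rather than at the nearest node.
* **Polygonization.** The covered street segments buffered by `buffer_width`
  (default 50 m) form the service-area footprint. We keep the footprint as
  the exact union of buffered segments ("capsules") with an exact
  point-membership predicate instead of materialising a boundary polygon:
  every downstream quantity is a population count obtained through point
  tests, so a vertex representation would add approximation without adding
  information. Footprints from different tools are in any case only
  comparable through the counts, never vertex-wise.
* **Overlay.** `areal` (default) splits each block's stratum counts by the
  fraction of its area inside the coverage, evaluated by deterministic
  cell-centre sampling on a 16×16 grid clipped to the block polygon (an even
  grid, so a block bisected by a straight boundary splits exactly 50/50);
  `centroid` assigns blocks all-or-nothing. Whether a published tabulation
  split blocks areally or assigned them whole is usually unstated, so both
  are exposed. Zero-area blocks fall back to the centroid rule with a
  warning.
* **Tabulation.** Within each stratum the accessed count is rounded by
  largest remainder against its complement, so `access + no_access = total`
  exactly; sex/age totals are sums of their strata. Percentages are
  `100·count/total` rounded half-up to two decimals (half-up, not banker's
  rounding, is what census tables use); the two shares then close to 100
  within 0.02. Empty strata report `NA` percentages rather than failing.

Increasing the radius or adding facilities can only grow the coverage, so
access counts are monotone — a property the tests exercise both on the
street-coverage length and through the final tables.

# The deprivation index

Block-level indicators (economic, social, cultural, structural) are
z-standardised, sign-flipped so that larger always means more deprived
(`deprivation_down` indicators such as literacy are negated), combined as a
weighted mean (equal weights by default), and cut into lower / middle / upper
classes by score terciles. Published deprivation classifications rarely state
their weights, normalisation or cut-points; equal-weight z-averaging with
tercile cuts is the minimal defensible reading of "combine, then classify
into three groups", and every element is configurable. Ties are broken by
`block_id`, so the classification is deterministic; a fully degenerate score
vector (e.g. perfectly cancelling indicators) is flagged on the result. The
ordinal coding (lower = 3, middle = 2, upper = 1) or a lower-class indicator
feeds Moran's I; an all-lower city yields a constant vector, which Moran's I
correctly refuses as zero-variance.

# The synthetic city

The generator is built for *testability, not realism*: it is the simplest
model that reproduces each qualitative structure the downstream statistics
must detect.

* **Streets** are a grid with interior nodes jittered uniformly by up to
  `road_jitter` (< half the block size, so blocks stay simple polygons);
  boundary nodes stay fixed, so the blocks tile the extent exactly. The grid
  is connected by construction; connectivity is nevertheless verified, with
  bounded regeneration and a diagnostic on failure.
* **Blocks** are the grid cells, sharing corners with the street nodes.
* **Population** follows a log-normal block density (`pop_sd_log`, default
  0.6) optionally modulated by Gaussian hotspot kernels, allocated to the six
  sex × age strata by largest remainder so the total is conserved *exactly*
  as integers. Default strata shares follow a young-city age pyramid (28%
  children, 66% working-age, 6% elderly; even sex ratio). Because facility
  placement is independent of the density surface, facility density is
  spatially decoupled from population density by construction.
* **Deprivation** derives from a latent simultaneous-autoregressive (SAR)
  Gaussian field $x = (I - \rho W)^{-1} e$ on the row-standardised rook
  lattice, with `deprivation_rho` (default 0.8) controlling spatial
  clustering. Observable indicators are monotone transforms of the latent
  field plus independent noise, mapped to plausible scales (unemployment
  rate in %, literacy rate in %, dependency burden, persons per room), plus
  the actual population density. At ρ = 0.8 the latent field's Moran z on a
  20×20 lattice is far above 1.96 essentially always — the clustered-poverty
  structure the pipeline should recover.
* **Facilities** are placed under complete spatial randomness, a
  Thomas-style parent/offspring cluster process (Poisson parents, Gaussian
  offspring spread defaulting to 2% of $\sqrt{A}$), or passed through as
  custom points (validated against the extent).

One master seed drives all sub-generators through a documented splitting
scheme (the master seed seeds R's RNG once; sub-seeds are drawn from it), so
identical configurations regenerate byte-identical interchange files.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real cities: realistic street topology (no dead-end culs de
sac, no arterial hierarchy, no barriers like rivers or railways), irregular
block geometry, vacancy and non-residential land use, correlation between
deprivation and population density, facility siting that responds to demand,
and measurement error in census counts. Results on synthetic cities validate
the *machinery*, not any empirical claim about a particular city.

# Numerical choices and problem sizes

* Tercile cuts distribute the `n mod 3` surplus blocks to the most-deprived
  classes first; any deterministic rule would do, this one is fixed and
  documented.
* Weights construction materialises an `n × n` distance matrix; the
  statistics were sized for block counts in the low thousands, which they
  handle in seconds.
* The brute-force oracle tests run ANN equivalence at n = 2000 and Moran
  equivalence at n = 500 (tolerances 1e-9 m and 1e-12); the CSR recovery
  study uses 200 seeds of 1000 points; the deprivation recovery study 100
  seeds of a 20×20 lattice. The bundled demonstration study uses a 40×40
  city (1600 blocks, 250 000 residents) with nested facility waves of
  29/33/78 — facility counts mirroring a three-wave municipal scenario —
  and smaller 12–16 block grids in the unit tests. These sizes are the
  package's own test-design choices: large enough that the sampling
  distributions are informative, small enough to iterate on.
* `coverage_area()` and the areal overlay are cell-centre counting schemes;
  their error is O(perimeter × cell), which the defaults keep near or below
  1% of the measured areas. They are deterministic: reruns give identical
  numbers.

# Limitations

* Single travel mode (walking) and uncapacitated facilities; no 2SFCA-style
  demand competition, no one-way streets or turn restrictions.
* The ANN z-score's boundary bias, discussed above.
* Moran's I values depend on the weights conceptualization; cross-study
  comparison requires identical weights.
* GeoJSON is the only geometry interchange format (by design: it is textual,
  diffable and universally convertible).
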