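---
title: "Small-area cluster analysis with Voronoi neighborhoods: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area cluster analysis with Voronoi neighborhoods: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

voroscan implements a small-area spatial epidemiology workflow for
cities where administrative boundaries are too coarse and conventional
base maps too sparse for neighborhood-level analysis. The motivating
application is urban firearm-injury surveillance: a hospital line list
of geocoded cases, a study area of a few administrative sections, a
satellite-derived population raster, and crowd-sourced named points
marking neighborhood centers. This vignette documents the models, the
tunable parameters, the synthetic-data generator that stands in for
private hospital data, and the numerical choices made where the design
was genuinely open.

## Neighborhood estimation by Thiessen polygons

Named seed points (e.g. OpenStreetMap "suburb" nodes, placed by
convention at the center of each neighborhood) are converted to areal
units by the Thiessen (Voronoi) tessellation: the cell of seed $s_i$ is
the set of locations nearer to $s_i$ than to any other seed,
intersected with the study area. `build_thiessen()` computes each cell
by successive half-plane clipping against the perpendicular bisectors
with all other seeds, starting from a bounding envelope padded by twice
the study-area diameter so every cell is closed before clipping; seeds
are processed in distance order with a radius cutoff, so cost is near
linear per cell in practice.

Design choices:

* **Planar coordinates only.** All operations (bisectors, distances,
  kernel bandwidths) assume planar geometry in meters. Users of
  geographic data must project first; the synthetic generator emits
  planar meters natively.
* **Tie-breaking.** A probe point equidistant from two seeds belongs to
  the lexicographically smaller unit name. The same rule orders the
  point-in-polygon assignment of cases and grid cells, which makes
  every spatial join deterministic and exactly conservative (each point
  counted once).
* **Seeds outside the study area** can end with an empty clipped cell;
  they are dropped with a warning and recorded in the `dropped`
  attribute rather than guessed at.
* **Distortion diagnostics.** Thiessen estimates are least reliable at
  the periphery, where seed density thins; `validate_partition()`
  reports each polygon's area relative to the median and flags extreme
  ratios (default beyond 3:1), alongside exact partition checks (area
  mismatch, pairwise overlap).

The tessellation's defining property — polygon membership equals
nearest-seed assignment — is tested against a brute-force oracle on
1,000 random probes, and the partition property (areas summing to the
study-area area within $10^{-6}$ relative) is asserted on every
synthetic layout.

## Aggregation

Population is attached by zonal summation with a **cell-center
containment rule**: a raster cell contributes its full count to the
unique neighborhood containing its center. Unlike area-weighted
apportionment this keeps conservation exact, and it matches the default
of the common raster-extraction tools. Cases are attached by
point-in-polygon with the same tie-break; cases outside every
neighborhood are returned as an exclusion list, mirroring the study
design in which patients residing outside the study area are excluded.
Rates are reported per 10,000 persons; a unit with cases but zero
population is flagged invalid rather than silently given an infinite
rate.

The kernel density surface (`kde_surface()`) is an axis-aligned
Gaussian product kernel with per-axis normal-reference bandwidths,
scaled to integrate to the number of points. It is exploratory output
only; no statistic downstream consumes it, and the bandwidth and
lattice size are configuration, not claims.

## Spatial autocorrelation

`queen_weights()` builds queen contiguity (any shared boundary point,
edge or corner) with either binary or row-standardized weights.
Contiguity is detected by vertex-to-boundary proximity within a snap
tolerance of $10^{-6}$ of the bounding-box diagonal, which is robust to
the floating-point jitter that clipping leaves on shared edges. Queen
contiguity with row standardization is the conventional default of the
areal-analysis tooling this workflow follows; both are explicit
arguments, not hidden defaults.

Global Moran's I is
$I = \frac{n}{S_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}$
on mean-deviations $z$. The analytic p-value is one-sided (greater)
under the **randomization assumption** — appropriate when reporting
evidence of positive autocorrelation of rates — with a
conditional-permutation pseudo p available for robustness
(`reps = 999` by default). The local statistic is
$I_i = (z_i/m_2) \sum_j w_{ij} z_j$ with $m_2 = \sum z^2/n$, so
$\sum_i I_i = n\,I$ for row-standardized weights; this identity is
asserted numerically in the tests. Local p-values use conditional
permutation (hold unit $i$, permute the remaining values onto its
neighbors), one-sided toward the observed direction, with the
pseudo-p convention $p = (1 + \#\{\text{as extreme}\})/(R+1)$.

Cluster quadrants (high-high, low-low, low-high, high-low) are assigned
from the signs of $z_i$ and its spatial lag, but only where the
**adjusted** p-value clears the significance level (default
$\alpha = 0.10$). Three adjustment regimes are provided, in increasing
conservatism:

1. `unadjusted` — raw pseudo p-values;
2. `fdr_units` — Benjamini–Hochberg with $m$ = number of units;
3. `fdr_links` — Benjamini–Hochberg with $m$ = number of nonzero
   directed links of the weights matrix ($L = \sum_i |N(i)|$).

BH was chosen as the FDR procedure throughout; the strictest tier's
$m = L$ follows the convention of applying the correction at the scale
of the neighbor-pair comparisons. By monotonicity of BH in $m$ the
tiers are nested: a unit significant under a stricter regime is
significant under every looser one, which the tests assert on synthetic
data with a planted hot spot.

## The discrete-Poisson scan statistic

Case counts $c_i$ in units with populations $p_i$ are modeled as
independent Poisson with means proportional to population under the
null. For a window $Z$ (a set of units) with observed count $c$ and
population-proportional expectation $E = C\,p_Z/P$, the
likelihood-ratio statistic for **elevated** rates is

$$\Lambda(Z) = c\log\frac{c}{E} + (C-c)\log\frac{C-c}{C-E}
\quad \text{if } c > E,\ \text{else } 0,$$

with $0\log 0 \equiv 0$. Windows are the classic circular family: for
every unit as center, the nested sets formed by adding units in order
of centroid distance, capped so the window population never exceeds a
fraction of the total (default 50%); the singleton window is always
included, identical member sets are de-duplicated, and distance ties
break by unit name. Inference conditions on the observed total $C$:
replicates redistribute $C$ cases multinomially with probabilities
$E_i/C$, and $p = \mathrm{rank}/(R+1)$ for the maximum statistic, with
$R = 999$ by default. A reported p at the floor $1/(R+1)$ prints as
"< threshold", and the reporting rule is $p \le$ threshold so that
floor-level clusters are reported at the conventional
`significance_threshold = 0.001` with $R = 999$.

Secondary clusters are reported in decreasing $\Lambda$ among windows
that share **no unit** with a higher-ranked reported cluster. Published
scan tables sometimes list overlapping clusters (a sub-window of the
most likely cluster reported separately); the weaker criterion — only
the window *center* must be new — is available as
`secondary = "no_centers_in_previous"` for table-replication work.
Ties in $\Lambda$ break toward the smaller window population, then the
lexicographically smaller center name, making the whole scan
deterministic for a fixed seed.

The space-time scan extends windows to cylinders: a spatial window
crossed with a contiguous day interval no longer than a fraction of the
study period (default 50%), with
$E = C \cdot (p_Z/P) \cdot u(\text{interval})$ where $u$ is the
interval's share of the temporal baseline. Because scanning is
one-sided for high rates, the maximizing interval must start and end on
days with cases, so only case-day endpoints are enumerated — an exact
reduction that keeps the cylinder family tractable. A cylinder spanning
the full period reduces exactly to the purely spatial window; cylinders
covering every unit (purely temporal clusters) are rejected unless
explicitly allowed. Two temporal baselines are supported, because the
handling of missing-record days in such studies is often unstated: the
default uses all calendar days; passing per-day weights (e.g. 0/1 for
missing/recorded) excludes missing days from the baseline instead.
Replicate scans prune windows whose best-possible statistic (all cases
on the cheapest single day) cannot beat the running maximum.

## Verifying published scan tables

Printed scan output tables carry enough arithmetic to be
internally checkable: per-cluster case counts and populations must
equal the sums of their member rows (population to ±1 for rounding),
and the relative-risk column
$RR = (c/E)\,/\,((C-c)/(C-E))$ can be inverted on a single row,

$$E = \frac{cC}{RR(C-c)+c}, \qquad P = \frac{C\,p}{E},$$

to recover the total at-risk population $P$ the analysis used
(`invert_total_population()`). The packaged transcription of the
spatial table yields $P \approx 3.565\times 10^6$ from the reference
row (the highest-RR single-unit cluster, numerically the
best-conditioned choice). Because the reference RR is itself printed to
two decimals, the inversion pins $P$ only to an interval;
`verify_scan_tables()` keeps the value in that interval most consistent
with the remaining printed RRs and then reproduces every spatial RR —
cluster-level and unit-level — to the printed two decimals. Space-time
RRs are *not* recomputed: they depend on how the original analysis set
its temporal baseline (in particular the treatment of the 133
missing-record days in the 406-day period), which the source does not
state; direct evaluation with a full-period baseline gives a cluster-1
RR near 5.4 against a printed 5.67, so the table is checked for
internal sums only.

## The synthetic study generator

`study_truth()` and `generate_study()` emulate the structure of the
motivating study so the full pipeline is testable without private data.
Defaults are the study-design constants: 16 sections, 106 neighborhood
seeds, a total population of 3,565,000 (the value recovered by the RR
inversion, rounded to the nearest thousand), a baseline rate tuned so
the expected case total is 248 over the 406-day period from 2019-11-22
to 2020-12-31, and 133 missing days placed as contiguous blocks of
14–28 days (records for the period are then 67% complete). Where the
study conditions are unstated, one realistic choice was fixed:

* **Section geometry**: a Voronoi partition of the study rectangle by
  uniform section seeds (convex, irregular, interior-disjoint), with
  the extent defaulting to a 15 km square — the scale of a dense urban
  core.
* **Seed placement**: rejection sampling with acceptance
  $\exp(-b\,d/d_0)$ in distance $d$ from the area centroid
  ($d_0$ = half the diagonal, `center_bias` $b = 1.5$ by default),
  emulating crowd-sourced label density thinning toward the periphery;
  $b = 0$ gives a spatially uniform process, which the tests verify by
  quadrat chi-square.
* **Population texture**: i.i.d. log-normal cell weights
  ($\sigma = 1$) on 100 m cells, normalized and integerized by largest
  remainder so the grid total matches the requested population
  *exactly*.
* **Cases**: the total is Poisson with mean `baseline_rate` ×
  population, scaled by any embedded excess risk; each case samples a
  cell proportionally to population times the relative risk of any
  covering embedded cluster (during its date window), jitters uniformly
  within the cell, and draws a date uniformly over non-missing days
  (reweighted inside cluster windows). A cluster with relative risk 1
  produces byte-identical output to no cluster at the same seed, a
  property the tests assert.

What the generator does *not* emulate: street networks, address text
and geocoding error, hospital catchment bias, day-of-week or seasonal
structure, and spatially correlated population texture. Passing tests
therefore demonstrate the statistical machinery under a faithful
discrete-Poisson world, not robustness to those real-data features.

## Operating characteristics and problem sizes

The test suite measures the methods' operating characteristics at sizes
chosen to keep a full run in a few minutes on one CPU:

* Monte Carlo p of the scan: uniform on its support under the null
  (500 meta-replicates of an 8-unit scan at $R = 19$; chi-square
  goodness of fit at $\alpha = 0.01$).
* Type-I error: 100 null scans at $R = 999$, 20 units, threshold
  0.001; at most 2 may report a cluster.
* Spatial power at study scale: 106 neighborhoods, $P \approx 3.565$M,
  $E[C] = 248$, a planted cluster of relative risk 5 over ~10% of the
  population; the most likely cluster must overlap the truth (Jaccard
  ≥ 0.5) in at least 90 of 100 seeded runs.
* Space-time localization, scaled geography: 36 units over the same
  406-day period, a 112-day burst of relative risk 10 over ~5% of the
  population; the most likely cylinder's interval must cover at least
  half the burst window in at least 80 of 100 seeded runs. The burst
  footprint and risk were fixed at values comparable to the strongest
  space-time clusters such studies report (unit-level relative risks
  well above 10).
* Exactness oracles: scan maximum vs exhaustive window enumeration for
  $n \le 6$; global Moran permutation p vs full enumeration at
  $n = 6$; checkerboard $I = -1$; BH against hand computation.

## Numerical notes and limitations

* Geometry is pure double-precision with tolerance-based predicates
  (coincident seeds at $10^{-9}$ m, contiguity snap at $10^{-6}$ of the
  extent diagonal); inputs with meaningful structure below those scales
  need rescaling.
* Clipping requires convex clip regions; Voronoi cells are always
  convex, so arbitrary simple study-area polygons are supported as
  *subjects*, but pathological nonconvex sections with matching
  nonconvex neighbors fall back to a grid estimate in the overlap
  diagnostic only.
* The raster interchange format is the plain-text ESRI ASCII grid,
  chosen so inputs and outputs remain human-readable and portable;
  georeferencing is the lower-left corner plus cell size, north-up.
* Monte Carlo inference for the space-time scan re-scans every
  replicate; at large unit counts this is the dominant cost, and the
  pipeline exposes `replications` so users can trade precision of the
  p-value floor against time.
* LISA pseudo p-values are conditional-permutation estimates; with
  heavy-tailed rates the analytic moments of $I_i$ are unreliable,
  which is why no analytic local p is offered.
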