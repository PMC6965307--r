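---
title: "Methods: population-exposure relative risk from source-resolved dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-exposure relative risk from source-resolved dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumepop)
```

## The problem and the model

Concentration maps alone overstate risk where nobody lives and
understate it in dense neighbourhoods exposed to moderate levels.
`plumepop` therefore computes, per 30 m grid cell $i$ and emission-source
category $j$ (industrial stacks, road traffic, or both combined), the
**relative risk of population exposure**

$$R_{ij} = \frac{pop_i \, C_{ij}}{\left(\sum_{i=1}^{n} pop_i \, C_{ij}\right)/n},$$

where $pop_i$ is the cell's population, $C_{ij}$ the annual-mean
concentration, and $n$ the number of cells in the normalization unit.
$R_{ij}$ is dimensionless, invariant to rescaling of either input, and
averages exactly 1 over the unit; $R > 1$ flags cells whose joint
population–pollution burden exceeds the unit mean.  Crossed with seven
demographic layers (total population; white, black and other races;
children, the elderly and other age groups) and three source categories,
the pipeline yields 21 risk surfaces.

The chain has four computational stages, each exposed as plain functions
so any stage can be run on real inputs or on the synthetic county.

### 1. Dispersion

Annual means come from a steady-state Gaussian plume with total ground
reflection evaluated at ground level,

$$C = \frac{Q}{\pi\, u\, \sigma_y \sigma_z}
      \exp\!\left(-\frac{c^2}{2\sigma_y^2}\right)
      \exp\!\left(-\frac{H^2}{2\sigma_z^2}\right),$$

with $Q$ the emission rate (g/s), $u$ the wind speed, $c$ the crosswind
offset, $H$ the release height, and Briggs *open-country* $\sigma_y$,
$\sigma_z$ curves selected by Pasquill stability class A–F.  This is a
deliberately simple stand-in for a regulatory dispersion model: it keeps
the interface (discrete annual-mean receptor concentrations per source
category) while omitting plume rise, downwash, terrain, deposition and
chemistry, which are out of scope.  No numerical agreement with any
specific regulatory model run is claimed.

Hourly meteorology is collapsed into a climatological wind rose — a
joint frequency table over 16 direction sectors, wind-speed classes and
stability classes.  Hours calmer than 0.5 m/s are dropped (the plume
equation degenerates as $u \to 0$; 0.5 m/s with renormalization over the
remaining hours is the usual regulatory convention) and frequencies are
renormalized over retained hours.  The annual mean at a receptor is the
frequency-weighted sum of steady states, using each cell's mean observed
speed and its sector midpoint direction.  Because the plume is exactly
proportional to $1/u$ within a (sector, stability) slice, speed classes
are collapsed analytically into a single weight
$\sum_{\text{bins}} f/u$ per slice before the kernel loop; this is an
exact rewrite, not an approximation.

Road sources are polylines discretized into sub-segments (≤ `seg_len`)
treated as point sources carrying length-proportional emission shares.
Annual tonnages convert to rates as metric tons over a 365-day year,
$Q = \text{tons} \times 10^6 / (365 \cdot 86400)$; the package reports
formatted rates truncated (not rounded) to two decimals, matching the
bookkeeping convention under which 237.79 t/yr prints as 7.54 g/s and
929 t/yr as 29.45 g/s.

### 2. Interpolation

Receptors sit at the centers of every `receptor_stride`-th cell,
emulating a coarse dispersion-model receptor net.  The gap to the full
grid is closed by inverse-distance weighting over the `k` nearest
samples, $w = d^{-p}$, evaluated at cell centers.  The method was chosen
for the framework because it is the standard pick for smooth
concentration surfaces; since the upstream comparison studies that would
fix $p$ and $k$ publish no values, the package uses the common GIS
defaults $p = 2$, $k = 12$ and exposes both.  IDW is exact at sample
locations (within a 10⁻⁶ m snap) and bounded by the sample range.

### 3. Dasymetric population mapping

Census-block counts are redistributed to cells using land-use class
density fractions as ancillary weights: within a block, a cell's weight
is the fraction of its land-use class, and each demographic count is
split proportionally.  Blocks whose cells all carry zero weight fall
back to a uniform spread, so the **pycnophylactic property** — every
(block, group) cell sum equals the block count — holds unconditionally;
it is the module's central test.  Cells are assigned to blocks by
cell-center containment rather than polygon-area intersection: at 30 m
cells against census-block polygons the difference is small, and the
rule is unambiguous and fast.  The default fractions (high-density
residential 1.0, low-density 0.4, commercial 0.1, undeveloped and water
0.0) are documented placeholders for empirically sampled values and are
fully configurable.

### 4. Risk, classification, hotspots, apportionment

The normalization unit for $R_{ij}$ defaults to the whole extent with
uninhabited cells **included** in $n$; whether such cells should count
is genuinely open, so a `risk_unit = "per-block"` switch normalizes
within blocks instead.  Inclusion keeps the denominator a plain mean and
preserves the reading "less than 1 means below the unit's mean risk".
If a unit has no population-weighted exposure at all the denominator is
0; risk is then set to 0 with a warning rather than NaN.

Concentration maps are classified into four and risk maps into six
natural-break levels.  The classifier is the **exact** Fisher–Jenks
dynamic programme (minimum total within-class sum of squared
deviations), not the common heuristic; inputs beyond `jenks_sample =
2000` values are subsampled under a fixed internal seed with the extremes
retained, keeping the call deterministic.  Class intervals are
half-open $(\text{lower}, \text{upper}]$ with the lowest class closed on
the left.  Frozen four- and six-level reference schemes ship alongside
for cross-run map comparability.

Hotspots are the cells at or above the $(1-f)$ quantile ($f = 0.10$ by
default); ties at the threshold are all included, so the selection never
depends on cell ordering.  The centroid is the unweighted mean of
selected cell centers — it locates the high area, not its mass — and the
centroid shift is the Euclidean distance (km) between the concentration
and risk hotspot centroids per source.  The shift distances reported for
any particular dataset depend entirely on that dataset; the package
reproduces the analysis form, not any published distance.

Source apportionment correlates, per demographic group, the
single-source risk surface against the combined-source risk surface over
the group's inhabited cells (Pearson r with the two-sided $t$ p-value).
The published scatter analyses this mirrors do not state the second axis
precisely; correlating single-source against combined-source risk is the
one reading that quantifies a source's contribution to overall exposure,
so it is the default, with `against = "total"` available to correlate
against total-population combined risk instead.  Groups with fewer than
3 usable cells or constant risk get an `NA` row with a status note and
never poison the other groups.

## The synthetic county

The generator builds, from one integer seed, a scenario with the spatial
structure the method assumes, so that every downstream property is
testable without downloads:

* a 20 × 20 km extent gridded at 30 m;
* 33 industrial point sources clustered in the south-eastern quadrant,
  sharing 237.79 t/yr of SO₂ (log-normal sizes, rescaled to the exact
  total);
* 6 road polylines crossing the extent through the urban core, sharing
  929 t/yr proportionally to length;
* 8760 hourly met records: a seeded prevailing direction plus a secondary
  mode and a uniform component, Weibull-like speeds (shape 2, scale
  4 m/s, floored at 0.5 m/s), and Pasquill classes drawn with
  daytime/night-time weighting (A–D by day, D–F by night);
* ~200 census blocks from recursive rectangle subdivision, with
  258,800 persons by default (a resident density of 647 persons/km²,
  the density of the county the defaults emulate) placed multinomially
  with weights decaying away from the core, and race counts drawn with a
  black-population share that rises towards the core so that demographic
  contrasts are non-trivial;
* a five-class land-use raster (high/low-density residential rings
  around the core, commercial strips along roads, undeveloped, a water
  body).

Race and age decompositions are drawn as multinomials conditioned on the
block total, so both sum to it exactly in every block.  The default
demographic mix (white 0.71 / black 0.13 / other 0.16; child 0.28 /
elderly 0.10 / other ages 0.62) was fixed once as plausible values for a
large US county.

What the generator does **not** emulate: real road topology, real block
shapes (its blocks are rectangles), serially correlated meteorology,
actual emission-inventory stack parameters (stack height defaults to
10 m and is configurable, since the emulated inventory publishes none),
or any statistical match to a real county's demography.  Tests passing
on this synthetic county therefore demonstrate the *correctness of the
computations and their invariants* (conservation, normalization,
superposition, optimality), not predictive skill on real data.

## Numerical choices

* Downwind distances below 1 m are clamped to 1 m (the near-field of a
  Gaussian plume is not meaningful at receptor scale); receptors exactly
  upwind or at the source get 0.
* Crosswind offsets beyond 12 lateral sigmas contribute exactly 0
  (exp(−72) ≈ 5 × 10⁻³²); the rule is applied identically in the scalar
  and the compiled field kernels so the two paths agree to rounding.
* Line-source discretization at `seg_len = 10` m for single-state
  calculations; the annual-field default is 100 m, which changes
  receptor values by well under 1 % at the ≥ 150 m receptor spacings the
  pipeline uses (the convergence is tested by halving).
* The default analysis scale — receptor stride 10 (300 m receptor
  spacing at 30 m cells), 100 m segments, 2000-value Jenks subsample —
  keeps a full 20 × 20 km county run to seconds; all three are config
  fields and can be tightened for production maps.
* Duplicate IDW sample locations with agreeing values are collapsed;
  conflicting values are an error naming the location.
* Jenks inner break values are midpoints between adjacent class-boundary
  data values; any strictly-between placement yields the same partition.
* The quantile threshold for hotspot masks is the type-7 sample
  quantile; "≥ threshold, ties in" makes the mask order-independent.
* All scenario randomness flows through one seed and the generator
  restores the caller's RNG state; identical seeds give byte-identical
  scenarios and hash-identical pipeline artifacts.

## Known limitations

* The dispersion stage is a Gaussian-plume stand-in: no boundary-layer
  parameterization, plume rise, terrain or chemistry.  Absolute
  concentrations are indicative; the framework's value is in the
  *relative* spatial structure that feeds the risk normalization.
* Cell-center block assignment slightly misallocates population along
  block edges at coarse grids; at the default 30 m it is negligible
  relative to census positional accuracy.
* Relative risk is an exposure-burden measure, not a health outcome; no
  concentration–response conversion is attempted.
* The correlation apportionment is descriptive.  It identifies which
  source's spatial pattern dominates combined exposure; it is not a
  receptor-model mass apportionment.
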