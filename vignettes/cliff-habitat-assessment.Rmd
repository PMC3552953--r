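---
title: "Remote assessment of cliff-nesting habitat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote assessment of cliff-nesting habitat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cliffs concentrate a disproportionate share of biodiversity — in Europe
roughly 44% of diurnal raptors nest on them, among these the colonial
griffon vulture (*Gyps fulvus*) and the endangered, territorial Egyptian
vulture (*Neophron percnopterus*). Because cliffs are essentially
vertical, they are nearly invisible to nadir-looking remote sensing, and
their survey has traditionally required expensive driving campaigns.
Street-level imagery taken from vehicles on public roads offers a free
horizontal perspective, but it covers only part of the road network and
can only resolve cliffs up to a limited distance.

`cliffscout` implements the quantitative machinery needed to evaluate
that trade-off end to end:

1. **Terrain**: an elevation-grid container with ESRI ASCII Grid I/O and
   slope as a dimensionless gradient (rise/run) by Horn's 3×3 weighted
   finite differences.
2. **Viewsheds**: exact line-of-sight visibility from observers placed
   along roads, giving the area surveyable on the ground versus from
   street-level imagery.
3. **Cliff classification**: slope thresholds taken from the slopes of
   occupied nesting cliffs — the minimum (`s_min`), 25th (`s_25`) and
   50th (`s_50`) percentile — and the three nested candidate-cliff maps
   they induce.
4. **Accuracy assessment**: stratified ground-truth sampling and the full
   thematic-map metric set (overall, producer's and user's accuracy,
   omission/commission error, Cohen's kappa).
5. **Survey economics**: a time/cost model for on-ground, remote and
   combined surveys.
6. **Detectability**: distance-to-covered-road analysis of which cliffs
   can be identified remotely, and which fine-scale features (white
   excrement spots, caves, vegetation) can be extracted.
7. **Synthetic data**: a seeded landscape generator so that the whole
   pipeline runs, and is tested, without any external dataset.

## Models and conventions

### Slope and thresholds

Slope is reported as a dimensionless gradient. The field thresholds this
mirrors (0.34, 0.63, 0.68) are consistent with gradients rather than
degrees or percent; we treat them as such throughout. Horn's method uses
the eight neighbours of a cell with weights 1–2–1; edge cells, and any
cell whose 3×3 window contains nodata, are nodata in the slope surface —
no values are invented at boundaries. Percentiles interpolate linearly
between order statistics (`stats::quantile` type 7), the common
statistical-software default; the same rule is used for distance
summaries. Classification uses `slope >= threshold`, so the
minimum-slope occupied cliff is itself captured by the `s_min` map, which
also guarantees the "producer's floor": every occupied cliff used to
derive the thresholds is classified cliff by `s_min`. A site's slope is
read from its single containing cell; a 3×3 neighbourhood maximum was
considered and rejected as a default because it inflates the calibration
sample on narrow scarps, but the reading is a one-line change if needed.

### Line of sight and viewsheds

A target is visible when the straight segment from the observer's eye
(ground + `eye_height`, default 2.5 m — a vehicle-mounted camera) to the
target point (ground + `target_height`, default 0) clears the terrain.
Terrain under the ray is the bilinear surface through cell centres. The
test evaluates that surface exactly where the ray crosses the grid lines
through cell centres (where bilinear reduces to linear interpolation
between two adjacent centres — the classic "R3" test) *and* at the
midpoint of every interval between crossings, because between crossings
the bilinear surface is quadratic along the ray and can bulge above the
chord; without the midpoints, grazing rays over rugged terrain are
misjudged in roughly 1–2% of cells relative to a densely sampled ray,
above the 1% discretization-tie allowance we hold ourselves to. Ties
within 1 mm (1e-9 m in the comparison) count as visible. A target in the
observer's own cell is always visible; nodata terrain blocks the ray,
and nodata under an endpoint is an error.

The same semantics are implemented twice: a pure-R reference
(`line_of_sight()`) and a C++ core used by `viewshed()` for speed. The
test suite checks them against each other cell-by-cell and both against
an independent dense-ray oracle (bilinear terrain sampled every
`cell_size`/10).

Observers are placed along roads at fixed arc-length spacing with both
polyline endpoints always included; the pipeline default spacing is
300 m, a compromise between fidelity and the quadratic cost of
observers × cells. `max_distance` is unlimited by default: per-square
viewshed areas are reported without a radius cut-off.

### Accuracy metrics and their conventions

All metrics derive from a 2×2 confusion matrix of reference (ground
truth) versus map class. Two conventions exist in the applied literature
for user's accuracy and commission error, and published cliff-map
assessments use the *reference-relative* pair — commission error as
`fp/(fp+tn)` and user's accuracy as its complement — rather than the
textbook map-relative `fp/(tp+fp)`. For the confusion counts
(tp 49, fn 1, fp 5, tn 45) the reference-relative pair gives (90, 0.10)
while the map-relative pair gives (90.7, 0.093); both are implemented and
labelled, with reference-relative as the default so the published table
is reproduced as printed. Cohen's kappa uses the standard single-rater
two-category closed form; under balanced reference classes (50/50) the
chance agreement is exactly 1/2 and kappa reduces to `2·po − 1`, an
identity the tests exploit. Note that the closed form applied to the
published confusion counts yields 0.88/0.58/0.44 for the three DEM maps,
not the printed 0.89/0.65/0.56; the printed coefficients cannot be
reconstructed from the printed counts under any standard kappa variant,
so the package asserts the closed-form values.

Ground-truth points are allocated to survey squares by largest-remainder
apportionment, with the two classes' remainders assigned from opposite
ends of the stratum list so per-square totals differ by at most one
(100 points over 7 squares gives 14–15 per square), then sampled
uniformly without replacement within squares. The pipeline samples
within the remotely surveyed area, mirroring the field protocol; when a
stratum cannot supply its quota there (small squares, sparse cliffs) the
pipeline reallocates the shortfall to strata with spare cells rather
than aborting — the strict per-stratum contract remains the default for
direct calls.

### Survey economics

The on-ground survey drives every drivable road at 30 km/h and costs
0.19 €/km (the package defaults; both configurable); the remote survey
costs no money. Effort is normalized per km² of viewshed. With
coincident fraction `f` (remote viewshed / ground viewshed), substituting
the remote survey on the coincident area saves
`f · viewshed_ground · (t_g − t_r)` minutes and
`f · viewshed_ground · c_g` euro, so the percentage money saving is
exactly `100·f` and the accounting identity
`combined = remote on coincident + ground on remainder` holds by
construction; both are property-tested. Savings percentages are computed
per square and then averaged, and travel to and from the squares is
excluded. A remote rate slower than the ground rate yields a negative
saving with a warning, not an error. Published mean savings depend on
per-square field data that were never released, so the model is validated
through its identities and synthetic squares rather than against those
means.

### Detectability

Distances are Euclidean point-to-segment minima over imagery-covered
polylines. Between-group distance comparisons use the Welch statistic
computed from group means and standard errors,
`|m1 − m2| / sqrt(se1² + se2²)`, the form recoverable from published
summaries; degrees of freedom and p-values via Welch–Satterthwaite are
secondary outputs when sample sizes are known. The 2×2 chi-square test
(for between-species detection counts) is Pearson's, with optional Yates
correction; neither variant reproduces the one published chi-square
value (0.01) from its own counts, so that value is not asserted
anywhere.

## The synthetic study system

The generator emulates the statistical structure the analysis assumes,
at the scale of one 10×10-km survey square (100×100 cells of 100 m):

* **Terrain** — a smooth two-scale sinusoidal base surface (amplitude
  80 m, wavelength 2 km; maximum base gradient ≈ 0.4) plus eight
  cuesta-shaped scarps: a 280-m climb over a 4-cell face (gradient 0.7,
  matching observed occupied-cliff slopes) and a gentle 16-cell
  backslope returning to base level. Cuestas run the full extent of
  their axis, so there are no artificial end walls. Parallel faces may
  not overlap (opposing ramps would cancel each other's gradient);
  perpendicular scarps cross freely since crossing gradients add in
  quadrature. The truth mask marks interior face cells — those whose
  whole 3×3 slope window lies on the face, where Horn recovers the
  designed gradient exactly.
* **Roads** — a paved lattice at 3-km spacing with a half-offset unpaved
  lattice. Each line is laid at whichever of several parallel candidate
  positions has the lowest mean slope along its course (roads follow
  valleys), and scarp faces keep at least a quarter spacing away from
  the nominal lattice — the negative road–cliff association real
  landscapes show. Imagery coverage is assigned to contiguous stretches,
  the last one split mid-road, so that exactly 49% of paved length is
  covered.
* **Sites** — 148 nesting cliffs drawn without replacement from truth
  cells; species occupancy in the shares 44/90/14 (griffon-only /
  Egyptian-only / shared) out of 148; independent feature flags with
  prevalences 0.77 (white spots), 0.59 (caves), 0.76 (vegetation);
  80% limestone.
* **Identification** — a visible site is identified with probability
  `plogis((d50 − d)/s)` with `d50` = 1000 m and `s` = 150 m, encoding
  the observed ≈1-km identifiability limit; conditional on
  identification, each field-recorded feature is seen remotely with
  probability 0.40/0.28/0.65. These conditional probabilities follow the
  published feature-detection shares; because identification itself is
  partial, the synthetic *unconditional* shares are proportionally
  lower.
* **Survey rates** — per-square per-km² times drawn from lognormals
  moment-matched to 0.91 ± 0.21 (remote) and 3.97 ± 2.94 min/km²
  (ground); the SDs convert the published standard errors over seven
  squares to between-square SDs. Zero SD gives exact rates.

Every draw descends deterministically from one seed, so a full run is a
pure function of (configuration, seed); the run manifest records the
seed and an MD5 hash over configuration plus key outputs.

What the generator reproduces well at this scale, across seeds: derived
thresholds near 0.34/0.63/0.7, ground visibility ≈ 95–99% (field:
97.4%), exact 49% paved-road coverage, and the stochastic ordering of
identified versus unidentified distances (Welch t ≫ 2). What it does
not: the identified-distance median settles around 500–700 m rather than
the ≈800 m seen at landscape scale, and identification rates around
40–55% rather than 66% — with the 1-km identification limit fixed, both
are governed by the distance distribution that a single 10-km square
with a 3-km lattice can produce, not by the detection model itself.
Remote visibility (≈70–85%) likewise exceeds the field's 48% because a
synthetic square has no large roadless interior. Passing tests therefore
demonstrate the correctness of the machinery and the qualitative
structure of the system, not that a real landscape would yield these
particular coverage figures. Real-data features deliberately not
emulated: road-network topology, lithology, vegetation occlusion of
sightlines, and observer-to-observer variation in imagery inspection.

## Numerical choices and degenerate inputs

* Grid geometry is half-open — a point on a shared edge belongs to the
  larger row/column cell — so every in-extent point maps to exactly one
  cell; cell centres and cell lookup are exact inverses.
* Visibility ties (terrain exactly at the sightline) resolve to visible,
  with a 1e-9 m tolerance.
* Wilcoxon signed-rank drops zero differences and uses the exact null
  for ≤ 25 untied pairs; if every pair ties, it returns `V = 0, p = 1`
  rather than an error — identical samples are a legitimate outcome of a
  comparison, not invalid input.
* Kappa with chance agreement 1 returns 1 if observed agreement is also
  1, otherwise errors; empty ratios (no reference cliffs, zero surveyed
  area, empty regions) raise errors naming the missing quantity.
* Degenerate paired comparisons inside the pipeline (e.g. identical
  viewsheds under full imagery coverage) are reported as absent rather
  than aborting the run.
* The logistic identification model is fitted by `stats::glm` and
  reparameterized to midpoint/scale form (`d50 = −b0/b1`,
  `scale = −1/b1`); recovery of `d50` within ±10% at n = 1000 is part of
  the test suite.

## Problem sizes

The default landscape is 100×100 cells; a full pipeline run (two
viewsheds, three maps, accuracy, economics, detectability) takes well
under a minute. The test suite's oracle comparisons use 12×12 to 20×20
grids where exhaustive and dense-ray checks are exact and fast; the
acceptance checks run 100 random 20×20 viewshed-versus-oracle grids,
1,000 synthetic economics squares, and an end-to-end run with 600 sites.

## Known limitations

* No earth curvature or atmospheric refraction in sightlines, and no
  vegetation occlusion: "visible" means terrain-visible.
* Planar metric coordinates only (UTM-like); no geodesy or reprojection.
* Two-class accuracy assessment only; no variance estimators for kappa.
* The cost model covers driving time and fuel only — no wages, travel to
  the study area, or multi-vehicle routing.
* Scarps are axis-aligned; terrain anisotropy beyond that is not
  modelled.
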