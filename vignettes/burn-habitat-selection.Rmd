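---
title: "Modelling habitat selection in burned landscapes with burnsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling habitat selection in burned landscapes with burnsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design

`burnsel` fits used/available habitat-selection models for animals in
post-fire landscapes. "Used" points are GPS fixes falling inside a burn;
"available" points are random locations drawn uniformly from the same
area, in equal number. A Random-Forest classifier separates the two
classes on habitat covariates, and the analysis reads selection off the
fitted model: which covariates the model keeps, and in which direction
their partial-dependence curves run.

The package has four layers: a raster data model with every covariate
derivation (`raster_grid`, `slope_aspect()`, `heat_load_index()`,
`flow_accumulation()`, `compound_topographic_index()`,
`distance_to_class()`, `burn_edge_distance()`, `focal_mean()`,
`focal_fraction()`, `nibble_reassign()`, `classify_burn()`); a synthetic
landscape generator (`landscape_config()`, `build_landscape()`); a
telemetry simulator and sampling design (`simulate_track()`,
`delineate_study_area()`, `sample_available()`, `build_table()`); and
the model-development procedure (`spearman_screen()`,
`redundancy_screen()`, `spatial_subsample()`, `mir_model_selection()`,
`permutation_significance()`, `partial_dependence()`, orchestrated by
`run_burn_model()`).

## Covariates and their conventions

All rasters are north-up grids of square cells (30 m by default) in a
projected equal-area coordinate system; distances are Euclidean in
metres between cell centres; nodata is `NA` in memory and a sentinel on
disk. Each covariate is also summarised at two focal scales — a 3×3
(90 m) window for fine-scale structure and a 27×27 (810 m) window for
patch-scale context — named with `_s` and `_l` suffixes. Edge cells use
the shrunken in-bounds window rather than padding, so no off-map habitat
is fabricated.

Decisions the operators embed:

- **Slope/aspect** use central differences (one-sided on the map edge);
  aspect is the downslope azimuth clockwise from north, and flat cells
  carry the sentinel `FLAT_ASPECT` (-1) rather than an arbitrary angle.
- **Heat load** uses the folded-aspect exponential-form equation
  (coefficients -1.467, 1.582, -1.500, -0.262, 0.607; fold
  `A' = |180° - |aspect - 225°||`), tagged `"mccune-keon-exp"` in the
  output metadata. Its source offers several variants; this one is
  symmetric about southwest and collapses to aspect-independence on flat
  cells because every aspect term is scaled by `sin(slope)`.
- **Flow routing** is single-direction D8, steepest drop over
  centre-to-centre distance, ties to the first neighbour in
  clockwise-from-north order. Flat cells drain iteratively toward their
  nearest resolved neighbour, so flats empty toward the nearest lower
  ground; true pits retain what they receive. The **compound topographic
  index** is `ln(a / tan β)` with the specific catchment area
  `a = contributing area / cell width` and slope floored at 0.001 rad —
  flat cells take the capped maximum instead of dividing by zero.
- A **draw** — the distance-to-draw covariate needs a concrete,
  computable definition of convergent drainage — is operationalised as a
  cell at or above the 0.95 quantile of flow accumulation; the quantile
  is an exposed argument.
- **Burn severity** splits at canopy-cover loss 50 %: the published cut
  prints "1–50 %" low and "> 51 %" high, leaving (50, 51] undefined, so
  the package uses low ≤ 50 < high to make the partition exhaustive.
- **Burn-edge distance** is defined inside the burn only; the map
  boundary counts as edge so the metric survives a burn covering the
  whole grid. By default any unburned cell — including an interior fire
  skip — acts as edge; `skips_are_edge = FALSE` flips that, since it is
  genuinely unknowable from the source analysis which convention was
  used.
- **Nibble** assigns each masked cell the code of its nearest valid
  cell; exact distance ties between classes resolve to the lower class
  code, making the operation deterministic.

## The synthetic landscape

The generator exists so the entire analysis is exercisable with known
truth. Every layer is built from correlated Gaussian random fields
(spectral synthesis: Fourier-filtered white noise, O(n log n), periodic
across the map edge), and every categorical layer is allocated by
rank-thresholding such a field, which yields coherent patches *and* hits
requested area fractions to within one cell. One master seed streams
fixed per-layer offsets, so layers are individually reproducible.

The burn mosaic builds a simply connected perimeter (largest connected
blob of a long-range field, morphologically closed and hole-filled) and
then places classes inside it **hierarchically**: each class takes the
top-ranked cells of its *own* field among the cells still unassigned,
smallest class first, with the largest class absorbing the remainder.
This matters: allocating all classes from bands of a single field makes
fire skips and high-severity burn exact rank-complements, and their
focal fractions then correlate beyond |ρ| = 0.8 — which would contradict
the emulated study, where the collinearity screen found no pair above
that threshold. With independent fields the processes are
distinguishable, as fuel moisture and fire weather are in real mosaics.

Class-conditional canopy-cover distributions overlap substantially
(new high severity 0–45 %, old regenerating 20–75 %, intact 30–95 %),
as real canopy layers do — residual trees and patchy regeneration keep
some cover even after severe fire. The class means still order as
severity dictates, which the tests assert. Precipitation rises linearly
with elevation plus correlated noise; land cover is allocated per
elevation band (spruce–fir concentrated high, dry forest low).

The shipped presets encode the two emulated study areas: `"tripod"`
(new burn: 63 % high severity, 8 % low, 21 % fire skips, 8 % old burn;
elevations 855–2390 m) and `"whiteface"` (old burn: 82 % high, 10 % low,
8 % skip; 1280–2222 m). Defaults elsewhere: 300×300 cells, latitude
48.5°, perimeter covering about half the map, correlation lengths of
3 km (DEM), 600 m (burn patches) and 300 m (canopy). No patch-size
statistics are available for fire skips in the emulated study areas, so
patch scale is configurable, not calibrated.

What the generator does **not** emulate: fire spread physics,
vegetation succession, anisotropy, real DEM roughness, and spatial
autocorrelation in telemetry error. Passing tests therefore demonstrate
that the *procedure* recovers known structure under realistic spatial
correlation — not that any particular real landscape behaves likewise.

## The telemetry simulator

Movement is discrete-choice: every 4 h the animal draws 20 candidate
endpoints (gamma step lengths, shape 2, mean 766 m; uniform headings)
and picks one with probability ∝ `exp(Σ β z)`, where `z` are covariates
standardized over the study area — the `β` are the synthetic ground
truth. The chosen location is recorded with probability 0.72, emulating
collar fix failure. Candidates that fall off-map or on nodata redraw
their *heading* but keep their length (a full redraw only if no
direction fits): redrawing both would truncate long steps near map
edges and bias the realized mean step below its configured value.

Availability is a design distribution: available points are drawn
uniformly over the area mask with replacement and may share cells with
used points. After covariate extraction, rows with any missing
covariate are dropped and the larger class is down-sampled at a fixed
seed, preserving the equal-count design. Study areas are delineated by
buffering the fix-to-fix path by the mean step length (766 m) and
rasterizing cell centres. Timestamps are abstract 4-h ticks; the
analysis never uses time of day. Available points are fixed per seed,
not regenerated per model run.

## Model development

1. **Screens** run on the full table, before the split, matching the
   narrative order of the emulated analysis: the redundancy screen flags
   near-exact linear combinations via rank-revealing QR (tolerance
   1e-7), then the Spearman screen flags pairs with |ρ| > 0.8 and drops
   the member with the lower importance in a quick pre-screen forest —
   any deterministic rule suffices here since the emulated analysis
   detected no such pairs, but the rule must be stated.
2. **Spatial subsample**: 80 % training / 20 % independent validation,
   with inclusion probability ∝ 1 / kernel intensity of the point
   pattern, so spatially clustered points are thinned. The default
   bandwidth smooths at a quarter of the mean bounding-box side with a
   box-window edge correction; the usual density-estimation
   rule-of-thumb is deliberately not used, because at these sample
   sizes it mistakes the sampling noise of a homogeneous pattern for
   structure and spreads per-point inclusion probabilities far from the
   nominal fraction. The bandwidth remains an exposed argument.
3. **MIR selection**: a forest on all covariates yields Model
   Improvement Ratios (importance / max importance, negatives floored
   at 0); for each threshold 0, 0.1, …, 1 the variables at or above it
   are refit and the trace records OOB and per-class errors. The final
   set minimises, lexicographically, OOB error, within-class error, and
   variable count, with remaining ties going to the larger threshold
   (parsimony). "Within-class error" is not pinned down by the source
   procedure; the default is the maximum of the two class errors
   (`within_class_stat = "mean"` is the alternative).
4. **Significance**: labels are permuted B = 1,000 times (configurable)
   and the model refit each time; the statistic is OOB accuracy — the
   holdout is never touched — and `p = (1 + #{null ≥ obs}) / (B + 1)`,
   so `p ≥ 1/(B+1)` always. B < 19 is rejected as unable to resolve
   α = 0.05.
5. **Partial dependence** substitutes each grid value into the focal
   column of every row and averages predicted use probability — exactly
   the brute-force definition, asserted against it in the tests.

The forest itself is `ranger` (probability forest, permutation
importances, seeded, single-threaded): the procedure around the learner
is the contribution here, not the tree-growing. Default 4,000 trees
mirror the emulated analysis; refits inside the permutation loop and
the MIR trace skip importance computation for speed, and tests use
reduced tree counts (100–200), which the config exposes.

Randomness is governed by one pipeline seed from which each stage
derives a fixed-offset sub-seed, so any stage is individually
reproducible and two runs with the same inputs are identical.

## Validation experiments and their sizes

The test suite runs three statistical experiments, sized to finish on a
single CPU in minutes while keeping their conclusions sharp:

- **Permutation calibration**: 100 replicate null tables (n = 400, six
  independent covariates), B = 99 permutations, 200 trees; the rejection
  rate at α = 0.05 must fall in the exact binomial 99 % interval.
- **Parameter recovery**: 20 landscapes (150×150 cells) with selection
  β = -1.5 on broad-scale new-high-severity fraction and +1.5 on
  broad-scale skip fraction, 2,000 used points each, 200 trees; both
  burn-class covariates must enter the chosen model with
  partial-dependence slopes matching the generating signs in ≥ 18 of
  20 runs. The recovery mosaic uses a more balanced composition
  (42/18/10/5/25 %) than the tripod preset: under skip-favouring
  sampling the tripod composition pushes the skip and high-severity
  fractions past the |ρ| = 0.8 screen threshold, and a screen that
  merges two near-duplicate encodings is doing its job — the recovery
  question is only well-posed when the two processes are statistically
  distinguishable, as they were in the emulated study. The β are placed
  on the broad scale because the 3×3 fractions of 600 m patches are
  nearly binary indicators: an indicator under an exponential selection
  function concentrates virtually all use in one class and makes a
  single covariate sufficient, collapsing the selection problem.
- **Generator/simulator fidelity**: achieved tripod fractions within
  ±2 points at 400×400; realized fix rate within ±3 points of 72 % and
  mean step within 2 standard errors of 766 m over 2,000 attempts.

## Known limitations

- Distance transforms and morphology come from EBImage (exact Euclidean,
  verified against brute force); raster I/O is ESRI ASCII grid + JSON
  sidecar, chosen as a plain-text, bit-exact single-band interchange
  format — no reprojection, resampling or multi-band imagery.
- The D8 router has no explicit depression breaching; closed basins
  terminate at their pits, which is adequate for synthetic smooth
  surfaces but would understate wetness below real sinks.
- The movement model has no behavioural states, home-range anchoring or
  dispersal; the habitat model has no individual-level random effects
  (the emulated analysis pooled animals after finding no individual
  variation).
- One printed worked example cannot be matched exactly: 789 of 13,972
  locations is 5.647 %, which rounds to 5.6 % at one decimal, not the
  5.7 % printed in the source summary; `burn_use_pct()` reports the
  honest arithmetic.
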