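---
title: "Measuring carrot shoot and root morphology from images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring carrot shoot and root morphology from images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrotmorph)
```

## The measurement problem

Carrot breeding targets both organs of the plant at once: a sturdy,
fast-growing cluster of petioles above ground and a storage root whose size
and shape define market class below it. Neither organ has a typical stem
axis — carrot internodes do not elongate, so the shoot *is* the fan of
petioles attached at the crown — and classic hand measurements (height,
biomass, a subjective shape descriptor) miss most of the architecture.
`carrotmorph` measures whole excavated plants photographed on a white
baseboard where a black horizontal line separates shoot (above) from
storage root (below), the standard staging for this kind of imagery.

The pipeline is a two-stage design. The first stage makes direct
measurements from each image independently: segmentation, biomass profiles,
and region morphometrics. The second stage predicts three traits that
cannot be read directly off a 2D silhouette — petiole width, petiole
number, and petiole length — using regression models trained on a table of
hand measurements for a subset of plants.

## Segmentation

An RGB photograph is reduced to a difference image `D = clamp(gray - S, 0)`
where `gray` is BT.601 luminance and `S` is HSV saturation scaled to the
same 0–255 range. On a white, unsaturated board both terms push background
values high, while plant tissue is either dark (shadow side, divider line)
or strongly saturated (orange root, green petioles), so `D` separates plant
from board far more cleanly than luminance alone. Otsu's method fixes the
threshold per image; pixels below it are foreground. Connected components
smaller than a configurable fraction of the image area (default 0.01%) are
removed — dust, fibrous-root wisps, and labels otherwise survive
thresholding and would perturb profiles downstream.

The divider line is found as the row whose median intensity over the
central columns is minimal; the median bridges the gap in the line where
the crown sits. Because the line is several pixels thick, the centre of the
contiguous run of near-minimum rows is returned (ties between separate
candidate lines resolve to the topmost). The mask is then split into shoot
and root strictly outside an exclusion band (default ±3 px) around the
divider, and the crown is placed at the divider row, at the column midpoint
of the first root row below the band. The root-top span anchors the crown
more reliably than the shoot bottom because storage-root tissue is
contiguous there, while petioles may straddle the gap. Plants whose
sections touch the image border cannot be measured reliably and are, under
the batch default, recorded as failures rather than measured wrongly.

All coordinates are `[row, col]` with rows increasing downward and 1-based
indices, following R convention.

## Biomass profiles

The **shoot biomass profile (SBP)** integrates the shoot mask over the
angular sweep of a half-elliptical grid anchored at the crown: each
foreground pixel gets a normalized elliptical radius
`rho = sqrt(((x-cx)/a)^2 + ((y-cy)/b)^2)` and is counted into one of `n`
half-open radius bins `[i/n, (i+1)/n)` (default `n = 1000`; `rho = 1` falls
in the last bin). Binning by radius is exactly the angular integral, and
the bin totals conserve the shoot pixel count — a property the test-suite
asserts exactly against an independent per-pixel implementation.

The grid axes are a genuinely open choice. For a single mask the default is
the shoot's own extent about the crown (inflated minimally so every pixel
has `rho <= 1`). The batch pipeline instead passes one **common grid** for
the whole population (`a` = half image width, `b` = crown row), because the
population-level interpretation of the SBP depends on an absolute radius
scale: with per-plant axes, profile shape no longer distinguishes a long
shoot from a short one, the first principal component loses its
biomass-magnitude meaning, and the SBP-based length predictor has nothing
to learn from. Staged photographs share camera geometry, so a common grid
is well defined.

The **root biomass profile** is the count of foreground pixels per row from
the first to the last nonzero row, resampled to `n` points by linear
interpolation at normalized row centres (`(i - 0.5)/L`). Sampling at
centres makes profiles invariant under integer upsampling of the mask,
which the suite checks at a 0.02 maximum absolute deviation after
normalization. For shape analysis the profile is normalized by its maximum
row sum (width) on top of the fixed-length resampling (length); whether the
original convention divided by the maximum row sum or the bounding-box
width is unknowable from the description, so the maximum row sum is used —
it is the profile's own scale and requires no second measurement.

## Classic morphometrics

`region_measurements()` reports area, bounding box, convex-hull area,
eccentricity, equivalent diameter, Euler number, perimeter, and solidity
for any mask. Fixed conventions, stated here because region properties are
notoriously implementation-dependent: foreground connectivity is 8, hole
connectivity is 4; the convex hull is taken over pixel squares (not
centres) so solidity can never exceed 1; second central moments include the
1/12 unit-pixel variance, keeping eccentricity strictly below 1 even for
one-pixel-wide regions; the perimeter is the count of exposed 4-neighbour
pixel edges, which is exact for axis-aligned rectangles. Pixel-to-cm
conversion is a configured `px_per_cm` factor (power 2 for areas);
automatic detection of reference markers is out of scope.

## The three petiole predictors

**Width.** The Euclidean distance transform labels every foreground pixel
with its distance to the background; on the medial skeleton
(Zhang–Suen thinning) twice that distance is the local full width of the
object. The skeleton EDT values are summarized as a 100-bin histogram
normalized to sum 1 — a fixed-length descriptor for partial least squares
(PLS) regression against ground-truth widths. The histogram cap must be
common across images to make descriptors comparable; the pipeline fixes it
at 30 px (about 6 cm of local width at typical calibration, comfortably
above any petiole and most leaf blades), while a standalone call defaults
to the image's own 99.5th EDT percentile.

**Number.** Digital shoot biomass (the foreground pixel count) divided by
the predicted average petiole width gives an area-to-width ratio that
scales with the number of petioles. This ratio (plus the raw area) is the
PLS input for count prediction. The prediction is left continuous;
rounding is the caller's decision. Two honest limitations are inherent to
this feature and worth stating. First, the ratio confounds petiole count
with mean petiole length, so its accuracy depends on the length spread of
the population — it cannot, even in principle, give a perfect count when
length varies freely. Second, above roughly 15 petioles 2D overlap removes
area faster than petioles add it, and counts are systematically
underpredicted; the test-suite documents this degradation directly.

**Length.** The SBP concentrates petiole mass at low radius and leaf-blade
mass near each petiole's tip radius, so profile shape encodes length. The
training SBPs are reduced by PCA (components up to 95% variance, capped at
10) and the standardized scores feed a feed-forward network with one
hidden layer (10 logistic units, linear output, weight decay `1e-2`,
maximum 500 iterations) trained from a seeded initialization — refits and
reloads are bit-identical. With uninformative (identical) profiles the
model collapses to predicting the training mean.

PLS component counts are selected by cross-validation; the "one-fold
holdout" description is ambiguous between leave-one-out and a single
train/validation split, so both are implemented and LOO is the default
(`cv = "loo"`). At full rank PLS1 equals ordinary least squares, which the
suite uses as one oracle; the other is an independent PLS implementation
(mixOmics) matched to 1e-10.

## Shape PCA

Population PCA is centred and unscaled. Shoot profiles enter raw, so PC1
reflects biomass magnitude; root profiles enter normalized, so components
reflect pure shape (taper, tip fill, mid-root thickening). Each
component's sign is fixed by making its largest-magnitude entry positive,
removing the arbitrary sign flip of eigenvectors. `eigen_sweep()`
reconstructs `mean + k * sd(scores) * component` for chosen multiples `k`,
the standard way to visualize what a component encodes.

## Repeatability and QTL support

Multi-environment trials are modelled as
`y = mu + G + E + B(E) + GxE + R` with all effects random. Components are
estimated by REML (lme4) by default; a closed-form expected-mean-square
estimator is available for balanced designs (`method = "anova"`), and
negative estimates are truncated at zero. Entry-mean repeatability is
`var_G / (var_G + var_GxE/t + var_R/(r t))` and the per-environment form is
`var_G / (var_G + var_R/r)`, with `t` and `r` computed as harmonic means of
per-genotype environment and replication counts so missing plots shrink
them appropriately. Estimator quality is accepted by simulation recovery
(mean bias below 10% over 500 balanced trials at σ²G = 4, σ²GxE = 1,
σ²R = 2 with 20 genotypes × 2 environments × 2 replications), not by
matching another package's output. Two-way ANOVA supplies significance for
G, E, and GxE; with unbalanced data its sums of squares are sequential,
which only matters off the balanced path.

QTL support utilities operate on marker names of the form `S{chr}_{bp}`:
`pve_from_lod()` computes `100 * (1 - 10^(-2 LOD / n))` — strictly
increasing, mapping `[0, Inf)` into `[0, 100)` — and
`lod_interval_width_mb()` converts flanking-marker positions into a support
interval width in Mb. A QTL table for a carrot F2 mapping population
(n = 316) ships in `inst/extdata/qtl_f2_records.csv` and
`scripts/acceptance.R` recomputes both quantities from it.

## What the synthetic generator emulates — and what it does not

Every stage is testable without photographs because the generator renders
carrot-like plants with complete ground truth: a white board, the black
divider with a central gap, an orange storage root whose silhouette
half-width is `(W/2)((1-b)(1-z/L)^k + b sqrt(1-(z/L)^2))` — taper exponent
`k` spans cylindrical to strongly conical, bluntness `b` spans pointed to
round-tipped, and the silhouette area has the closed form
`W L ((1-b)/(k+1) + b π/4)` used as a rendering oracle — and green petioles
fanning from the crown, each ending in a circular leaf blob.

Default population parameters emulate a single biparental F2 staged on the
standard board: 5–15 petioles; petiole width 4–14 px; per-plant mean
petiole length truncated-normal (mean 210 px, sd 30 px, bounds 140–290 px,
about 14% CV — within-cross variation, not the several-fold range of a
diversity panel); leaf-blob radius 1.5–1.7 × petiole width, reflecting the
allometric coupling of blade size to petiole cross-section within one
genetic background; root length 180–300 px, maximum width 50–100 px,
`k ∈ [0.3, 2.5]`, `b ∈ [0, 0.6]`; calibration 10 px/cm. Petiole bases are
spread along the crown top rather than stacked on one point — plants are
deliberately staged with leaves spread apart, and petioles attach around
the crown circumference. Any range can be overridden, including to a
degenerate single value, which the tests use to isolate one factor at a
time.

The generator does not attempt photorealism: no shadows, soil, specular
highlights, uneven lighting (a Gaussian noise knob exists but defaults to
0), no fibrous roots, no root branching, no label cards. Passing tests
therefore demonstrate the pipeline's logic — conservation, geometry,
model wiring, recoverability of known signals — not robustness to the
lighting failures that dominate real-world losses. Correlations achieved
on synthetic populations are upper bounds for field images, not estimates
of them.

## Problem sizes and numerical choices

The test-suite exercises a seeded 100-plant population at full canvas
(600 × 720 px) for the end-to-end checks, 50-plant small-canvas
populations for per-module properties, and 500 simulated trials for
variance-component recovery; the whole suite runs in a few minutes on one
CPU. Other fixed numerics: Otsu on a 256-level histogram of the difference
image; profile bins half-open with the top edge in the last bin; PLS
stops adding components when the residual covariance norm underflows
(degenerate designs fall back to an intercept-only model with a warning);
network inputs and targets are standardized; harmonic means are taken over
per-genotype counts.

## Known limitations

Single-plant images only; no lens or perspective correction; calibration
must be supplied, not detected; the count predictor's feature set bounds
its accuracy as described above; per-environment repeatability is
undefined with a single genotype and GxE with a single environment (both
are flagged, not silently filled); and the shape PCA is a symmetric,
profile-based analysis — bending and asymmetry descriptors are out of
scope by design.
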