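# carrotmorph

Automated shoot and root morphometrics for single-plant carrot photographs.

Carrot breeders need objective, quantitative measurements of both organs of
the plant: the fan of petioles that makes up the shoot (carrot internodes do
not elongate, so petioles *are* the shoot architecture) and the storage root
whose size and shape define market class. `carrotmorph` measures whole
excavated plants photographed on a white baseboard with a black horizontal
divider line — shoot above, root below, crown in the central gap — and turns
each image into segmentation masks, biomass profiles, classic morphometrics,
and model-based predictions of petiole traits. Population-level tools cover
shape principal components, repeatability from variance components, and
QTL-support statistics. A procedural generator of carrot-like images with
exact ground truth makes the whole pipeline testable without photographs.

## Methods at a glance

- **Segmentation** — grayscale minus HSV saturation (scaled to the same
  range), Otsu threshold, small-component cleanup; divider located by
  row-median darkness; crown anchored at the column midpoint of the root
  top. Output: shoot mask, root mask, crown point, QC overlay.
- **Shoot biomass profile (SBP)** — `SBP(r) = ∫ MASK(r, θ) dθ` over a
  half-elliptical grid anchored at the crown: each shoot pixel is binned by
  its normalized elliptical radius into `n = 1000` bins, so
  `Σ SBP = shoot area` exactly.
- **Root biomass profile** — foreground count per image row over the root
  extent, resampled to 1000 points; normalized by length and width
  (`max = 1`) before shape analysis.
- **Petiole width** — Euclidean distance transform sampled on the
  morphological skeleton (2 × EDT = local width), summarized as a 100-bin
  histogram and regressed on ground truth by PLS with LOO-selected
  components.
- **Petiole number** — digital shoot biomass divided by the predicted
  petiole width, PLS against true counts.
- **Petiole length** — SBP principal components feeding a one-hidden-layer
  feed-forward network (seeded, deterministic).
- **Repeatability** — variance components of
  `y = μ + G + E + B(E) + GE + R` (REML, or expected mean squares on
  balanced designs); entry-mean repeatability
  `σ²G / (σ²G + σ²GE/t + σ²R/(rt))` and per-environment
  `σ²G / (σ²G + σ²R/r)` with harmonic-mean `t`, `r`.
- **QTL support** — `PVE = 100 (1 − 10^(−2·LOD/n))` and 1.5-LOD support
  interval widths in Mb parsed from `S{chr}_{bp}` marker names.

## Worked example

```r
library(carrotmorph)

dir <- file.path(tempdir(), "demo")      # synthetic fixture images
out <- file.path(tempdir(), "demo_out")  # measurement outputs
truth <- make_fixtures(30, seed = 42, dir = dir)

res <- run_measure(dir, out, px_per_cm = 10)
#> measured 30 images, 0 failures

# train the three petiole predictors on 24 plants, predict the rest
tr <- truth[1:24, c("image_id", "petiole_count",
                    "petiole_length_cm", "petiole_width_cm")]
names(tr)[2] <- "petiole_number"
pred <- run_predict(out, tr, px_per_cm = 10, seed = 1)
```

Held-out plants 25–30 (true vs predicted):

```
     image true_n pred_n true_len pred_len true_w pred_w
 plant_025      8    8.8     20.4     21.9   1.16   1.16
 plant_026      8    8.9     22.8     23.1   0.78   0.78
 plant_027     13   12.2     21.4     19.5   0.82   0.85
 plant_028     10    9.3     19.3     18.5   0.43   0.43
 plant_029     10   11.1     25.3     22.7   0.49   0.48
 plant_030     11    8.5     16.4     18.1   0.68   0.76
```

Petiole number and width are in counts and cm; lengths in cm (10 px/cm
calibration). Shape PCA of the width-normalized root profiles concentrates
the variation of this 30-plant fixture on the taper axis:

```r
profs <- carrotmorph:::read_profile_csv(file.path(out, "root_profile.csv"))
pca <- fit_population_pca(profs)
#> root shape PCA: PC1 96.2%, PC2 2.8%, PC3 0.8%
```

QTL-support statistics from a LOD score and flanking markers:

```r
pve_from_lod(32.49, 316)                             # 37.72 (%)
lod_interval_width_mb("S2_42846844", "S2_43581817")  # 0.73 (Mb)
```

A thin command-line driver over the same functions ships in
`inst/scripts/carrotmorph` with subcommands `measure`, `predict`,
`make-fixtures`, `shape-pca`, `repeatability`, and `qtl-utils`.

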