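# zctexture

Quantification of immunofluorescence staining texture for receptor
clustering studies, built around the **zero-crossing (ZC) linear-density
score**. The motivating system is the collagen receptor DDR1, whose surface
stain coarsens in stages after ligand stimulation — fine puncta, then
connected linear clusters, then dense aggregates — with the dense stage
showing double-walled structures in super-resolution images whose gap is
filled by collagen and phospho-receptor signal. The package provides, as
plain R functions over matrices and a few light S3 carriers:

* **`zc_score()`** — the core statistic. The image is locally
  average-subtracted (running mean over a ~10 µm window, renormalised at
  patch edges, recentred to exactly zero in-patch mean), and intensity
  profiles along random lines through the patch are sampled at 1-px steps
  with bilinear interpolation. The score is the mean number of zero-level
  crossings per µm of line over typically 2000 lines:

  ZC = (1/N) Σᵢ cᵢ/ℓᵢ  [crossings/µm]

  Higher = finer texture; lower = coarser, denser signal; exactly invariant
  to intensity scaling. Analytic anchors: a grating of period P yields
  4/(πP) crossings/px over uniform line angles, and a Gaussian random field
  with correlation length ℓ yields the Rice rate 1/(πℓ).
* **`make_cell_mask()`** — the ImageJ-equivalent mask pipeline (threshold
  strictly above background, two rounds of 3×3 dilate → fill holes →
  erode, largest component), validated against a pixel-level oracle.
* **`segment_texture_patches()`** — two-scale Gaussian-gradient
  segmentation of 1–4 representative texture patches per cell, excluding
  bright membrane ruffles and out-of-focus regions.
* **`mean_intensity()`, `anchor_normalize()`, `fraction_positive()`,
  `densitometry_fractions()`, `normalize_by_expression()`,
  `group_compare()`** — per-cell quantification and the normalisation /
  statistics conventions used around such experiments.
* **`extract_profile()`, `minmax_normalize()`, `fwhm()`,
  `detect_double_wall()`** — multi-channel line profiles (200 nm line
  width), full-width-at-half-maximum measurement, and detection of
  double-walled (wall/filler) ridge structures.
* **`generate_scene()`, `generate_timecourse()`** — a seeded synthetic
  fluorescence scene generator with ground truth (cell silhouette,
  structure centrelines, ruffle and illumination fields) emulating the
  four texture classes, so the entire pipeline is testable without
  microscope data.
* **`run_timecourse_analysis()`** — the end-to-end pipeline: scenes →
  masks → patches → ZC scores → phospho quantification → per-experiment
  anchoring → ANOVA with post-hoc tests, written as tidy CSVs plus a
  summary plot.

## Worked example

```r
library(zctexture)

sc <- generate_scene(scene_config(texture_class = "linear_cidc",
                                  char_length_um = 0.4, seed = 7))
sc
#> <scene> linear_cidc, 256 x 256 px @ 0.1 um/px, channels: ddr1, py, char length 0.4 um

mask <- make_cell_mask(sc$channels$ddr1)
mask
#> <cell_mask> 17206 px (26.3% of frame), background level 4.02

patches <- segment_texture_patches(sc$channels$ddr1, mask)
patches[[1]]
#> <texture_patch #1> 15378 px (153.78 um^2)

zc_score(sc$channels$ddr1, patches[[1]], n_lines = 2000, seed = 42)
#> <zc_result patch 1> ZC score 0.7985 crossings/um (2000 lines, mean length 9.59 um, 10 um window)
```

The cell mask covers the simulated cell (26% of the frame); one patch of
154 µm² carries the texture; its ZC score, 0.80 crossings/µm, sits between
the punctate (~1.4) and aggregate (~0.7) classes — the linear-cluster stage
is intermediate in coarseness, as it should be.

A full synthetic time course, with per-experiment anchoring of the
phospho signal:

```r
report <- run_timecourse_analysis(analysis_config(
  n_experiments = 2, cells_per_time = 4,
  image_shape = c(160L, 160L), n_lines = 200, seed = 3
))
report
#> <timecourse_report> 24 cells analysed, 0 excluded; times: 0, 10, 60 min
#>   time_min n_cells zc_mean  zc_sem py_norm_mean py_norm_sem positive_pct
#> 1        0       8  1.4652 0.03044    1.084e-19     0.03788            0
#> 2       10       8  0.9816 0.02951    3.503e+01     1.41124          100
#> 3       60       8  0.7048 0.02676    1.000e+02     2.41219          100
```

Mean ZC falls monotonically with stimulation time (1.47 → 0.98 → 0.70
crossings/µm) — the texture coarsens — while the anchored phospho signal
rises from 0 to 100 A.U. and the positive-cell fraction saturates.

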