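---
title: "Quantifying immunostain texture with the zero-crossing score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunostain texture with the zero-crossing score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zctexture)
```

## The problem

Collagen-binding receptor tyrosine kinases such as DDR1 redistribute on the
cell surface after ligand stimulation: a fine punctate immunostain becomes a
network of connected linear clusters within minutes, and coarse dense
aggregates after roughly an hour. The degree of clustering is biologically
meaningful (dense aggregation correlates with receptor phosphorylation), but
"coarseness" is hard to score by eye without bias. This package implements
an automated texture statistic for exactly this setting — homogeneous
fluorescence textures inside a single cell — together with the morphological
mask pipeline, per-cell intensity quantification, multi-channel line-profile
analysis, and a ground-truthed synthetic scene generator used to validate
every stage.

## The zero-crossing (ZC) score

A texture patch is first *locally average-subtracted*: a running mean over a
square window (default 10 µm on a side) is subtracted from the image, the
mean being taken over in-patch pixels only so patch edges do not bias it,
and the result is recentred so its in-patch mean is exactly zero. This
removes background variation from uneven staining or illumination; what
remains varies around zero because of texture alone. We call this the
reference image.

Random lines are then drawn across the patch: a uniformly random in-patch
anchor pixel, a uniformly random direction in $[0, \pi)$, extended both
ways to the patch boundary and sampled at 1-pixel steps with bilinear
interpolation. For each line the number of times the sampled profile
crosses zero is divided by the line length; the ZC score is the mean of
these per-line densities over `n_lines` draws (2000 by default):

$$\mathrm{ZC} = \frac{1}{N}\sum_{i=1}^{N} \frac{c_i}{\ell_i}
\quad [\text{crossings}/\mu m].$$

A finer texture fluctuates faster, so it crosses zero more often: higher ZC
means finer texture, lower ZC means coarser, denser signal. Because zero
crossings of $cI$ and $I$ coincide for any $c>0$, the score is exactly
invariant to the signal's amplitude (and hence to exposure or expression
level), which the test suite asserts as bit-exact equality under a shared
seed.

Two closed-form results anchor the implementation. A sinusoidal grating of
period $P$ pixels crossed at angle $\theta$ has density
$2|\cos\theta|/P$; averaging over uniform angles gives
$\mathbb{E}|\cos\theta| = 2/\pi$, hence $4/(\pi P)$ crossings per pixel.
And a stationary Gaussian random field with correlation function
$\rho(r) = \exp(-r^2/2\ell^2)$ has, by Rice's formula, crossing rate
$\sqrt{-\rho''(0)}/\pi = 1/(\pi\ell)$ along any line. The acceptance suite
reproduces both (3% and 10% tolerances respectively).

### Numerical choices

* **Zero samples.** Exact zeros carry the previous non-zero sign, so a
  profile that touches zero without changing sign is not a crossing; this
  avoids double counting at interpolated zeros. An exhaustive oracle over
  all $\pm 1$ sequences of length ≤ 12 pins the counting rule.
* **Aggregation.** The score is the mean of per-line densities; pooled
  counting (total crossings / total length) is available via
  `aggregate = "pooled"` and agrees closely on homogeneous patches.
* **Sampling bias.** Counting sign changes of 1-px bilinear samples misses
  occasional paired sub-pixel crossings; on the analytic grating this is a
  stable ≈ 2% deficit, within the stated tolerance. Step size at or below
  the pixel pitch keeps the deficit small for band-limited signals.
* **Windowless mode.** For closed-form comparisons on stationary fields
  (`window_um = NULL`) only the global in-patch mean is subtracted. A 10 µm
  running mean high-passes a field whose correlation length is a sizeable
  fraction of the window and visibly raises the crossing rate above the
  Rice prediction; the windowed mode is for real images with background
  drifts, the windowless mode for fields that are zero-mean by
  construction.
* **Degenerate lines.** Lines with fewer than 3 samples are redrawn (with
  a retry cap), so slivers of a fragmented patch cannot contribute
  zero-length ratios.

## Cell masks and texture patches

The cell mask reproduces the classic ImageJ recipe: threshold strictly
above a per-image background level, then two rounds of dilate → fill holes
→ erode with a 3×3 structuring element; the largest connected component is
the cell. Outside-the-frame pixels count as background and hole filling
uses 4-connectivity; a pixel-level brute-force oracle asserts exact
equivalence on random grids. When no background level is supplied, the
histogram mode plus 3×MAD of the sub-median pixels is used — a documented
interpretation, since the original level was chosen manually per image.

Texture patches are segmented with Gaussian-gradient signatures at two
scales: pixels are kept where the fine-scale (0.15 µm) gradient magnitude
indicates texture, and excluded where the smoothed intensity is anomalously
high at the ruffle scale (0.5 µm, above the 99th in-cell percentile,
dilated by 0.5 µm) — bright membrane ruffles — or anomalously low at the
coarse scale (2 µm, below the 2nd percentile) — out-of-focus or empty
regions. The retained region is closed, hole-filled and reduced to at most
4 connected components of at least 2 µm², matching the 1–4 regions of
interest per cell the method expects. The exact construction of the
two-scale signature is an interpretation (the idea, not the formulas, is
prescribed); every threshold is a documented, configurable parameter.

## Intensity quantification and normalisations

`mean_intensity` averages strictly inside the mask. `anchor_normalize`
rescales per-cell values affinely so two designated condition means map to
0 and 100 A.U. (used both for unstimulated/stimulated anchoring and for
within-experiment normalisation of phospho signal). `fraction_positive`
reports the percentage of cells above a positivity threshold with its
binomial standard error; the default threshold, mean + 2 sd of the
unstimulated condition, replaces the manual judgement used originally.
`densitometry_fractions` normalises each lane's phospho band to its total
band and expresses the ratios as percentages of the blot-wide sum, so they
conserve 100 exactly. `normalize_by_expression` implements "weighting to
the median expression" as a plain ratio — the simplest reading of an
ambiguous description; the convention is recorded in the result so a
different weighting could be swapped in knowingly. `group_compare`
delegates to `aov` with Bonferroni, Tukey or Dunnett post-hoc procedures —
these are standard routines, deliberately not re-derived.

## Line profiles, FWHM and double-walled structures

`extract_profile` samples every channel with identical geometry along a
segment at 1-px steps, averaging across a configurable perpendicular width
(default 0.2 µm). `fwhm` measures a peak's full width at half maximum with
linear interpolation at the half level; the baseline defaults to the
profile minimum (background-subtracted convention), with a zero-baseline
flag, because the original convention is unstated. `detect_double_wall`
operationalises the filler-in-gap geometry seen in super-resolution images
of dense receptor aggregates: two wall-channel maxima flanking a trough at
least 30% of the range deep, with the filler channel peaking inside the
trough; failures return reason codes rather than errors.

## The synthetic scene generator

Each scene is one cell: a star-convex random silhouette occupying 20–60% of
the frame, a diffuse in-cell baseline (15% of the channel amplitude — the
cytoplasmic stain level the mask threshold keys on), and class-specific
structures: isotropic Gaussian puncta (σ = FWHM/2.355), random-walk
polylines with a Gaussian cross-section, coarser sparse blobs, or
double-walled polylines (two parallel ridges at the configured gap in the
receptor channel, a single centred ridge in the collagen/phospho
channels). Corruption applies a smooth multiplicative polynomial
illumination field (fractional peak-to-trough set by
`illumination_amplitude`), bright ruffle blobs (4× amplitude, σ 0.3 µm)
within 1 µm of the cell boundary, Poisson shot noise on intensities read
as expected photon counts, and Gaussian read noise. Patterns are rendered
at unit amplitude and scaled last, so amplitude scaling is exact by
construction.

Default study conditions: pixel size 0.1 µm (typical widefield sampling;
never stated in the source material, so configurable everywhere), with
0.04 µm used for double-wall scenes because a 0.3 µm gap with ~0.14 µm
walls is below the widefield sampling limit — precisely why such
structures required super-resolution imaging. The stimulation time course
maps 0 min → punctate (characteristic length 0.2 µm, 3 structures/µm²),
5–30 min → linear clusters (0.4 µm, 0.4/µm²), ≥ 45 min → aggregates
(0.8 µm, 0.3/µm²). The characteristic lengths follow the 0.2/0.4/0.8 µm
ladder used throughout the validation suite; the densities were chosen
once as realistic for the depicted morphologies — dense enough that texture,
not empty baseline, dominates each patch (in the sparse-spot regime the
crossing rate is density-limited and no longer decreases with structure
size). The phospho-channel amplitude rises linearly with stimulation time
so positivity fractions and anchored means behave like a real activation
time course.

What the generator does **not** emulate: optical PSF/SIM reconstruction
artefacts, 3-D structure, photobleaching, multi-cell fields, chromatic
shift, or spatially varying focus. Passing tests therefore demonstrate the
*computational* contracts (morphology, counting rules, invariances,
analytic rates, orderings) on images with realistic noise and confounds —
not performance on any particular microscope's data.

## Problem sizes and determinism

Validation runs use 128–256 px frames, 100–20 000 lines per patch, cohorts
of 3 cells × 3 time points × 50 replicates, and 60–100 labelled scenes per
class for the double-wall operating point; these sizes give comfortable
margins for every stated tolerance while keeping a full run inexpensive.
All randomness flows through a single seed per entry point (scene seeds,
line seeds, cohort seeds are derived sub-seeds), so scenes are
bit-reproducible and pipeline runs write identical CSVs given identical
configurations.

## Known limitations

* The ZC score needs an in-focus, single-cell crop; cropping is an input,
  not a capability.
* The two-scale patch segmentation is an interpretation of a briefly
  described procedure; its thresholds matter most for sparse textures and
  are exposed as parameters.
* The grating deficit (~2%) is intrinsic to 1-px sampling of bilinear
  interpolants; finer step sizes would reduce it at proportional cost.
* `fwhm` assumes a single dominant peak between its half-level crossings;
  overlapping peaks closer than their widths are reported as one.
* The densitometry and flow-cytometry helpers operate on already-extracted
  band/median tables; gel image analysis and FCS gating are out of scope.
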