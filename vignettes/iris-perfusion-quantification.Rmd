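---
title: "Quantifying iris perfusion on en-face OCTA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying iris perfusion on en-face OCTA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octairis)
```

## The measurement model

En-face OCTA maps blood flow as image brightness. Perfusion is
summarized by two densities over a region of interest $R$:

$$\mathrm{VAD} = \frac{\#\{\text{vessel pixels} \in R\}}{\#R},
\qquad
\mathrm{VSD} = \frac{\#\{\text{skeleton pixels} \in R\}}{\#R},$$

where the vessel pixels come from binarizing the flow image and the
skeleton is the one-pixel-wide centerline of that mask. VAD measures
the area fraction perfused (sensitive to vessel caliber and
dilation), VSD measures vessel length per unit area (sensitive to the
number of visible vessels). Both are unitless fractions in $[0,1]$ and,
because the skeleton is a subset of its mask,
$\mathrm{VSD} \le \mathrm{VAD}$ holds for every region — this is an
invariant of the implementation, not an empirical observation.

The measurement chain for one eye (`measure_eye()`) is: estimate a
threshold, binarize, remove specks, skeletonize, and evaluate both
densities per segment; the chain is repeated `n_replicates` times
(default 3, mirroring triplicate manual measurement) and averaged.
With the default deterministic threshold the replicates are identical
by construction and the mean equals a single pass; a
threshold-jitter mode exists to emulate operator re-measurement
variability, driven by seeded substreams so that even "noisy"
replication is bit-reproducible.

### Iris measurement windows

Iris scans (3×3 mm) are acquired with the frame running from the pupil
center to the 9 o'clock corneal limbus, i.e. the limbus at the
image-left edge. The measurement windows are anchored at the
pupillary margin on that meridian:

* full window: 150 px above and below the margin row, 150 px from the
  margin column toward the limbus (300×150 px);
* 1/3 and 2/3 segments: the innermost 50 and 100 px of that span, all
  sharing the pupil-margin edge — nested windows with areas in exact
  ratio 1:2:3.

Two readings of the segment scheme are possible and the source
description does not disambiguate them: nested windows anchored at the
margin, or disjoint tertile bands. The package defaults to **nested**
(`build_iris_rois(mode = "nested")`) because the iris vasculature is
densest at the pupillary margin, so nested windows over an inward
density gradient naturally produce the observed ordering
VAD(1/3) > VAD(2/3) > VAD(full); disjoint bands are available via
`mode = "disjoint"`. Similarly, the "full segment" is read as the
150-px window rather than the entire pupil-to-limbus distance; both
the half-height and span are parameters, so either reading can be
configured.

Laterality metadata (`eye = "OD"/"OS"`) is carried but never flips the
geometry: the 9 o'clock construction refers to the scan frame as
acquired. Windows that exceed the frame are clipped with a warning and
the clipped area is used as the denominator, avoiding a silent bias
toward the in-frame part.

Coordinates everywhere in the public interface are 0-based, origin
top-left, with half-open intervals; conversion to R's 1-based indexing
happens only inside the indexing helpers.

## Binarization

The source analysis computed VAD/VSD in MATLAB without stating its
segmentation rule, so the rule here is a package design choice: a
**global Otsu threshold** (parameter-free, the de-facto default in
OCTA quantification), optionally preceded by white top-hat background
flattening, with a local mean-plus-offset adaptive rule as the
configurable alternative (`binarize_config()`). Two details matter:

* the threshold is *estimated* over the measurement window when one is
  supplied (as `measure_eye()` does with the full segment window),
  because the iris frame also contains the dark pupil and the brighter
  sclera, whose gray levels would contaminate a whole-frame histogram;
  the threshold is then *applied* to the whole frame;
* connected components smaller than `min_object_px` (default 4 px,
  8-connectivity) are removed before skeletonization, so isolated
  speckle does not contribute spurious skeleton fragments. The value
  is deliberately conservative — at the phantom's default noise level
  misclassified background pixels are rare and nearly always smaller
  than 4 px.

A constant image admits no separating threshold; `binarize_angiogram()`
returns an all-background mask with a warning rather than an error, so
batch runs survive degenerate frames.

## Skeletonization

VSD needs a centerline whose pixel count measures length. Classical
parallel thinning schemes (Zhang–Suen, Guo–Hall) erode line ends by
roughly half the vessel width, which biases VSD down for short
segments. The package instead uses **border-sequential
topology-preserving thinning**: in each iteration, four directional
passes (N, S, W, E) delete border pixels that are *simple points* —
pixels whose removal does not change the local topology,
characterized by a Yokoi 8-connectivity number of 1 — and never delete
endpoints (pixels with exactly one neighbor). The border set of each
pass is frozen at its start, so each pass peels at most one layer and
cannot collapse a region. By construction the result is a subset of
the mask, preserves the number of 8-connected components, is
idempotent, and keeps centerline length up to end effects: the
skeleton of a 5×100 px bar has 98 pixels (the midline, minus one-pixel
end effects), where Zhang–Suen-style schemes give 96–97. The kernel is
implemented in C++ (Rcpp), as is the 8-connected component labelling,
since both are per-pixel algorithms.

Skeleton "length" is the plain pixel count, matching the pixel-ratio
convention of OMAG-style VSD. A diagonal-corrected variant (unit
horizontal/vertical links, $\sqrt2$ diagonal links) is available via
`compute_vsd(diagonal_corrected = TRUE)` for users who want metric
length; it is not the default because the pixel-count convention is
what the published densities use.

## The phantom generator

`generate_iris_phantom()` produces the study conditions for testing:
a dark pupil disk, iris-stroma background (gray 80), brighter sclera
beyond the limbus circle (gray 120), and radial vessels (gray 200)
drawn as quadratic Bézier curves from the pupillary margin toward the
limbus with jittered control points (minimal tortuosity model). With
`density_gradient` $g > 0$ a vessel's radial extent is a truncated
exponential with rate $g$, so the number of vessels crossing a given
radius decays roughly like $e^{-gt}$ — emulating the real iris, where
vasculature is densest at the pupillary margin. Additive Gaussian
speckle (SD 10 gray levels by default) is clipped to [0, 255] and
quantized to 8 bits. The ground-truth mask records exactly the
rendered vessel pixels, so every downstream metric can be checked by
direct pixel count.

Defaults were chosen once to make the phantom resemble the published
densities: the frame is 420×420 px (the device's en-face pixel
dimensions are not a published constant, so the frame is
configurable; 420 px comfortably contains the 300×150 px window),
pupil radius 80 px with center (210, 360), limbus column 60, and 140
vessels of width 1–3 px, which yields a ground-truth 1/3-window VAD
near 0.29 — inside the published iris range — with
`calibrate_n_vessels()` provided to retune the count to any target
density by direct measurement on the emitted mask. Macular phantoms
(6×6 mm, 480×480 px) use 90 frame-crossing vessels of width 2–5 px,
landing near the published retinal VAD of ~0.5.

What the phantom does **not** model: physically realistic OCT speckle
statistics (the noise is additive Gaussian, not multiplicative),
projection or motion artifacts, pigment masking of deep vessels, 3D
volume rendering, or pathology (hemorrhage, neovascular tufts).
Passing tests on phantoms therefore demonstrate the correctness of
the geometry, metrics and statistics — not segmentation robustness on
clinical images.

`generate_cohort()` simulates per-eye metric records directly:
truncated-normal draws (reject-and-resample outside (0, 1), since the
metrics are fractions) with per-eye substream seeds derived from a
master seed by counter, so reproducibility is independent of
iteration order. `design_rvo_cohort()` and `design_dr_cohort()`
encode the two study arms; their 1/3-segment and retinal means/SDs
are the published group summaries (e.g. iris 1/3 VAD
0.34 ± 0.07 / 0.29 ± 0.07 / 0.26 ± 0.03 for RVO / fellow / control,
n = 21 each). The 2/3- and full-segment values are not published; the
package fixes them once so that within every group the mean and the
SD both decrease from the 1/3 to the full segment (e.g. RVO VAD
0.34/0.30/0.28 with SD 0.07/0.05/0.04), reproducing the reported
segment-trend pattern in which the innermost segment has the highest
average and the largest deviation.

## The statistics layer

* **Normality**: `ks_normality()` is a Lilliefors test — the normal
  parameters are estimated from the sample, so classic
  Kolmogorov–Smirnov critical values would be anticonservative. The
  Dallal–Wilkinson p-value approximation (via nortest) requires
  n ≥ 5; smaller samples are an error.
* **Variance homogeneity**: `levene_test()` centers at the group
  means (the SPSS default) rather than medians.
* **Group comparison**: pooled-variance t-tests and one-way ANOVA;
  the two-group ANOVA F equals $t^2$ exactly, which the tests assert
  as an identity. Pairwise contrasts in `one_way_anova()` and
  `group_comparison_report()` are *uncorrected* two-sided pooled
  t-tests by default, mirroring the P1/P2/P3 presentation of clinical
  tables that state no correction; Bonferroni and Holm switches are
  provided for users who want family-wise control.
* **Summary-statistic ANOVA**: `anova_from_summary()` reconstructs
  the omnibus F from printed means/SDs/sizes,
  $F = \frac{\sum_i n_i(\bar x_i - \bar x)^2/(k-1)}
           {\sum_i (n_i-1)s_i^2/(N-k)}$,
  and agrees with the raw-data ANOVA to $10^{-10}$ relative error on
  simulated data. Note that reconstructing a published F from
  *rounded* printed summaries will generally not reproduce the
  printed F exactly; the reconstruction is exact only for exact
  inputs.
* **Sample size**: `sample_size_two_sample_t()` searches integer n
  from 2 upward against the exact noncentral-t power
  (noncentrality $\delta\sqrt{n/2}/\sigma$, df $2n-2$), returning the
  smallest n whose power reaches the target — the convention of
  standard power software. At $\alpha=0.05$, power 0.8,
  $\delta=0.1$, $\sigma=0.05$ this gives 6 per group; a normal
  approximation gives ~4 and understates the requirement.
* **Display**: table p-values are formatted to three decimals, so
  p < 0.0005 prints as "0.000" as in clinical tables; stored values
  keep full precision.

One caveat is inherited deliberately: fellow eyes are compared to
their own patients' affected eyes with *unpaired* tests, ignoring
within-subject correlation, because that is the analysis the report
layout reproduces. A mixed-effects treatment is out of scope.

## Numerical and degenerate-input choices

* Zero pooled variance in the t-test: equal means return t = 0,
  p = 1; unequal means are an error (infinite statistic).
* All-identical ANOVA groups (0/0 F): defined as F = 0, p = 1.
* Chi-square requires strictly positive marginals; it is Pearson's
  statistic without continuity correction.
* Landmark auto-detection (`locate_landmarks()`): the pupil is the
  largest dark connected region (below half the median gray level)
  of plausible size (0.2 %–35 % of the frame), its radius half the
  dark run length along the centroid row; the limbus column is the
  split of the smoothed centroid-row profile maximizing local
  left-minus-right mean contrast (the sclera plateau is brighter
  than the stroma); failures instruct manual annotation, and a
  landmark JSON always takes precedence verbatim.
* Empty ROIs (zero area) and out-of-bounds ROIs are errors; empty
  masks skeletonize to empty skeletons.

## Test and simulation scale

The test-suite phantoms use a scaled-down geometry (240×240 px frame,
80/90-px windows) so that the full suite runs in about a minute; the
scaling preserves every invariant being tested (window ratios, density
gradient, ground-truth bookkeeping). Calibration checks use 1,000
null replicates (type-I error asserted within 0.05 ± 0.02) and
ordering-recovery checks 500 seeded cohort replicates. At the
published effect sizes the strict sample-mean ordering
RVO > fellow > control has probability just above 0.95, so the
ordering-recovery check sits close to its own threshold by
construction — a property of the published effect sizes, not of the
implementation.

## Limitations

The package quantifies; it does not diagnose. No deep-learning
segmentation, projection-artifact removal, perfusion-deficit mapping,
FFA-based grading or device raw-signal processing is included.
Phantom realism is deliberately minimal (see above), and clinical
binarization choices (threshold rule, speck size) should be validated
against expert annotation before use on patient data.
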