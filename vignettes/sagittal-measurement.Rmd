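---
title: "Measuring spinal sagittal parameters from landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spinal sagittal parameters from landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesag)
```

## The measurement model

A lateral whole-spine radiograph is reduced to eleven landmarks: the
centers of both femoral heads, the center of the sacrum, and the
anterior/posterior endpoints of four endplates — S1, L1 and T1 superior,
C2 inferior.  Twelve signed angles are measured from them.

Every angle is the angle between two vectors.  Its magnitude is the
arccosine of the normalized dot product; its sign comes from the 2-D cross
product, oriented by an explicit frame convention so that rotation toward
the patient's anterior side is positive.  Under this one rule the clinical
sign conventions fall out together:

* a slope is positive when the endplate drops anteriorly (the sacral
  slope of a normal standing adult is positive);
* an incidence is positive when the endplate perpendicular lies anterior
  to the pelvic-tilt line;
* regional Cobb angles are negative for lordosis, positive for kyphosis;
* pelvic tilt is positive when the S1 midpoint lies posterior to the
  femoral-head midpoint (retroversion).

With these signs three identities hold *exactly*, not approximately:
`PI = PT + SS`, `XI = XS + PT` for X in {L1, T1, C2}, and the six test
parameters (`LL = L1I − PI`, `TK = T1I − L1I`, `C2_7L = T1I − C2I`,
`L1S = L1I − PT`, `T1S = T1I − PT`, `C2S = C2I − PT`) equal their directly
measured counterparts.  The test suite verifies each identity to 1e-6
degrees on phantom-generated and on arbitrary random landmark sets (where
the additive identities hold modulo 360°, since reported angles live in
(−180°, 180°]).

### Conventions that had to be chosen

Several details are underdetermined by the clinical definitions alone;
the package fixes them once and tests them everywhere:

* **Coordinates** are 0-based raster pixels, origin top-left, y downward;
  "up" is −y.  The patient's anterior direction (`+x` or `−x`) is a
  mandatory explicit input (`frame_convention()`), never inferred from
  the image: lateral films are acquired facing both ways and a silent
  guess would flip every sign.
* **Endplate vectors** run posterior → anterior; the endplate
  perpendicular is that vector rotated 90° toward "up".  This fixes the
  otherwise ambiguous perpendicular branch.
* **The pelvic-tilt line** runs from the femoral-head midpoint to the
  midpoint of the S1 superior endplate.  The `sacrum_center` landmark is
  carried as a detection target only — the endplate midpoint, not the
  sacrum body center, defines the line.
* **Degenerate geometry** (coincident endplate endpoints, a zero
  pelvic-tilt line) raises an error naming the offending landmarks.  A
  silent `NaN` would propagate invisibly into cohort statistics.
* Angles are computed and held in full floating precision; rounding to
  two decimals happens only when a human-facing CSV report is written.

### Numerical note

The angle magnitude is evaluated as `atan2(|cross|, dot)` rather than
`acos(dot / |v1||v2|)`.  The two are mathematically identical, but the
arccosine loses half the significant digits near 0° and 180° (its
derivative diverges); the `atan2` form is fully conditioned everywhere,
which matters because parallel-endplate configurations — where regional
angles are exactly zero — are legitimate test cases.

## The phantom generator

No public radiograph corpus accompanies this problem, so the package
generates its own ground truth.  A phantom is parameterized by exactly
the five independent angles the method measures — PI, PT, L1I, T1I, C2I —
plus rendering controls.  Construction is the forward model of the
definitions: the S1 endplate is placed at slope `SS = PI − PT` at the end
of a pelvic-tilt line tilted `PT` from vertical, and the L1/T1/C2
endplates are placed at their target slopes on a centerline whose local
direction interpolates the endplate perpendiculars linearly in arc
length.  Measuring a phantom recovers its targets to floating precision
(tested at 1e-6° over 100 random feasible specifications).

The cohort sampler draws the five independent angles from independent
normal distributions truncated to published clinical minima and maxima
(defaults in `cohort_defaults()`: e.g. PI 51.76 ± 12.47° on
[27.94, 80.18]).  Sacral slope and the six test parameters are always
derived, never sampled, so every synthetic subject satisfies the angle
identities internally.  Two consequences are deliberate:

* truncation shifts the expected mean of asymmetrically bounded
  parameters slightly away from the nominal mean (about +1.2° for the L1
  incidence); the tests compare empirical means against the closed-form
  truncated-normal mean;
* inter-parameter correlations present in real cohorts (e.g. PI with
  lumbar lordosis) are *not* modeled, because the reference tables do not
  publish them.  The sampler is a test harness, not a population model.

Vertebral-body *positions* between the inflection levels carry no angular
information, so they are a rendering choice: the centerline's lateral
drift is compressed about the S1 midpoint whenever a steep configuration
would leave the canvas.  This keeps every in-range draw feasible (the
sampler rejects nothing, so cohort statistics stay unbiased) while
preserving all twelve angles exactly.

Rendering draws femoral-head discs and vertebral-body quadrilaterals
(half-plane rasterization of convex quads), then applies separable
Gaussian blur and additive Gaussian noise, all seeded.  The default
canvas is 270 × 810 px, a 4× downscale of a typical 3240 × 1080 px
whole-spine film; resolution is a rendering detail, not part of the
method, and tests use smaller canvases.  What the phantom does *not*
emulate: ribs, soft tissue, scoliosis, implants, exposure gradients —so a
detector trained on phantoms demonstrates the cascade mechanics, not
clinical readiness.

## The detection cascade

Detection is decentralized over three orders, each narrowing the region
of interest for the next:

1. **Order 1** sees the full image and predicts three coarse region
   centers: hip (femoral heads), lumbar/pelvic (S1, sacrum center, L1)
   and cervical (T1, C2 — T1 is assigned to the cervical region).
2. **Order 2** sees a crop around each region center and predicts the
   centers of the member vertebrae (five in all).
3. **Order 3** sees a crop around each vertebra center and predicts its
   final landmarks; every canonical landmark belongs to exactly one
   order-3 head.

Crop transforms are exact integer-offset mappings, so coordinates
round-trip between frames to machine precision (tested below 1e-9 px).

The published method's contribution is this ordering and the
mean-absolute-error loss, not a specific network: architectural details
are deferred to its antecedents.  The package therefore treats the
regressor as a pluggable fit/predict contract and ships a deliberately
small default: a multi-output *linear* regressor on block-mean
downsampled pixel intensities (12 × 30 cells for order 1, 14 × 14 for
crops), trained full-batch by adaptive-moment gradient descent (Adam) on
the MAE loss.  Adam is a member of the gradient-descent family — each
weight moves against the gradient of the loss scaled by a learning rate —
and converges far faster than plain first-order steps on the
piecewise-linear MAE surface, which matters on a single CPU.

Two training choices follow standard cascade practice where the source
method states only the narrowing principle:

* training crops for orders 2–3 are centered on the *ground-truth*
  targets plus substantial uniform jitter (default ±18% of the crop
  extent), with several jittered crops per image (default 3); inference
  crops come from the previous order's predictions.  The jitter teaches
  each stage to correct the displacement the previous stage will hand it
  — without it the deeper orders merely memorize "the vertebra sits at
  the crop center" and inherit every upstream error;
* a single seed controls the 9:1 train/validation split, the jitter and
  the initialization, making training bit-reproducible.

Problem sizes: the package's own end-to-end check trains on 200 phantoms
at 162 × 486 px, 400 epochs per head, which runs in well under a minute
on one CPU and leaves 20 held-out subjects.  On that synthetic validation
split every parameter's success-rate curve is monotone and reaches 0.8 at
a finite threshold, which the evaluation reports.  No claim is made that
these thresholds transfer to real radiographs — that would require real
training data.

Predictions falling outside the image are clamped to its bounds and
flagged per landmark (`clamped` column) rather than silently filled.

## Agreement statistics

* **Success rate** is the fraction of cases whose absolute error falls
  *strictly below* a threshold (`<`), matching the usual phrasing;
  inclusive comparison is available via an argument, since ties are
  measure-zero on real data but not on grids.  The default threshold
  grid is 0.5°–10° in 0.5° steps, configurable.  Curves are computed per
  parameter, not pooled.
* **Bland–Altman** uses the n−1 sample SD and limits mean ± 1.96 SD; the
  limits-cover-95% property is tested by simulation at n = 1e5.
* **Agreement summaries** report MAE, SD of absolute error, Pearson r
  with its two-sided p, and R² = r².  Zero-variance input makes the
  correlation undefined; it is reported as `NA` with a warning, never a
  silent `NaN`.
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measure — is computed from the ANOVA mean squares
  `(MSR − MSE) / (MSR + (k−1)MSE + k(MSC − MSE)/n)`, with 95% confidence
  bounds from the McGraw & Wong (1996) F-based formulation and a p-value
  from `F = MSR/MSE`.  Tests cross-check the estimate against an
  independent `aov()`-based computation on random matrices and against a
  hand-computed 3 × 2 example (ICC = 2/3).  The degenerate
  all-equal-ratings matrix is rejected explicitly.

On synthetic cohorts the derived-vs-direct comparison of the six test
parameters returns MAE at floating-epsilon scale and R² rounding to 1.0 —
the derivation equations are identities, so this is a consistency check
of the implementation, not an empirical finding about measurement
accuracy.

## Known limitations

* The phantom's independence assumption between the five sampled angles
  is synthetic; real spinopelvic parameters are correlated.
* The default detector is a linear pixel regressor sized for CPU
  training on phantoms; clinical images would need a stronger regressor
  and real annotations behind the same cascade interface.
* Distance-based parameters (e.g. the sagittal vertical axis) and
  vertebral numbering from images are out of scope.
* DICOM ingestion is an extension point; the package reads PNG input.
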