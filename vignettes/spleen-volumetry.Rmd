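---
title: "Cavalieri spleen volumetry: methods and design notes"
author: "splenometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cavalieri spleen volumetry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splenometry)
```

## The measurement model

The spleen is an irregular organ whose size, shape and position vary widely
between individuals; it is clinically palpable only when enlarged to two to
three times its reference size, so imaging-based volumetry is the practical
route to detecting modest enlargement. This package implements the standard
stereological pipeline for estimating an organ's volume from a stack of
parallel MR sections, together with the single-slice morphometry used to ask
whether one axial slice could stand in for the full volumetric measurement.

**Cavalieri estimator.** Given parallel sections a fixed centre-to-centre
distance $d$ apart (slice thickness plus inter-slice gap), starting at a
uniformly random offset within one spacing, the estimator

$$\hat V = d \sum_{i=1}^{n} a_i$$

is unbiased for the true volume, where $a_i$ is the organ's area on section
$i$. Areas come from binary segmentation: $a_i$ is the number of organ
pixels times the in-plane pixel dimensions $d_x d_y$. Two exact identities
anchor the implementation and its tests: with zero gap the estimate equals
the voxel-count volume bit for bit, and prepending or appending empty
sections changes nothing.

**Precision (coefficient of error).** A single systematic section sample
carries a predictable relative standard error. With
$A=\sum a_i^2$, $B=\sum a_i a_{i+1}$, $C=\sum a_i a_{i+2}$ over the
zero-trimmed profile, the default predictor is

$$\mathrm{CE} = \frac{\sqrt{(3A-4B+C)/12}}{\sum a_i},$$

the Gundersen–Jensen smoothness-class-0 form usually attributed to
Cruz-Orive for irregular objects; the smoothness-class-1 variant (the same
numerator over 240) is available as `variant = "gj240"`. On a constant
profile the expression collapses to $\mathrm{CE} = 1/(n\sqrt 6)$, which the
tests pin to $10^{-12}$. A CE at or below 0.05 is the conventional
acceptability bound. With fewer than three sections the lag products are
undefined and the CE is reported as missing with an explicit reason rather
than extrapolated — a single slice cannot certify its own precision, which
is the quantitative face of the one-slice question.

**Morphometry conventions.** The procedures behind the published
single-slice numbers are under-specified in the literature this package
models, so each measurement states its convention explicitly:

- *Circumference*: holes are filled, the region is eroded by the 3×3 cross
  (a pixel survives only if its 4-neighbourhood is inside) and the boundary
  is the difference — an 8-connected, exactly one-pixel-wide contour. The
  circumference is the contour pixel count times the pixel length. A
  digitized $s\times s$ square gives exactly $4s-4$ pixels; on smooth
  convex shapes the count under-runs the Euclidean perimeter (about −11%
  on a rasterized disk) because diagonal runs contribute one pixel per
  step. This is the conventional contour count, deliberately not a Crofton
  or sub-pixel estimator; the bias is pinned, not hidden.
- *Pixel length*: a single "pixel length" only exists for isotropic
  pixels; when $|d_x-d_y|/d_x > 1\%$ the geometric mean $\sqrt{d_x d_y}$
  is used with a warning.
- *AP / transverse diameters*: tight bounding-box extents along the image
  axes ((occupied rows) $\cdot\, d_y$, (occupied columns) $\cdot\, d_x$), the
  natural reading for supine axial imaging; rotation-invariant Feret
  calipers are available behind `feret = TRUE`.
- *Spleen length*: craniocaudal slice extent — occupied sections times $d$
  — the common radiological convention for axial stacks; its
  discretization error is bounded by one slice spacing on convex organs
  aligned with the slicing axis.

**Segmentation.** The original measurements were made by human operators
thresholding and painting images. The scriptable stand-in is: optional
rectangular ROI (JSON sidecar, 0-based pixel coordinates), Otsu's
between-class-variance threshold over the ROI intensities, then retention
of the largest 26-connected 3D component. Each piece is replaceable — a
fully manual mask can be supplied as NIfTI and measured identically.

## The synthetic study

No patient images are available, so the package generates its own ground
truth at two levels.

**Phantoms.** Ellipsoids (closed-form volume $\tfrac43\pi abc$),
superellipsoids (closed form
$8abc\,\Gamma(1+1/p)^3/\Gamma(1+3/p)$, verified in tests against an
independent Monte-Carlo membership integral) and lobulated "bumpy"
ellipsoids whose radial modulation $(1 + A\sin 3\theta\cos 2\phi)$ has no
elementary volume and is integrated by spherical quadrature on a
$2000\times2000$ grid (4×10⁶ nodes, far beyond the accuracy the voxel-level
comparisons need). Voxelization uses a centre-point membership test —
the discrete analogue of binary manual segmentation — on a grid with
0.15 × 0.15 cm in-plane spacing and $d$ = 0.8 cm (0.6 cm thickness +
0.2 cm gap) by default, typical abdominal-MRI geometry chosen once since
the modelled study never states its protocol spacing. The slice stack
starts at a uniformly random offset in $[0, d)$, satisfying the Cavalieri
random-start requirement; tests verify the mean estimate over 200 random
offsets lands within 0.5% of the analytic volume.

**Cohort.** The generator reproduces the modelled study population:
110 male and 235 female subjects; spleen volume 223.5 ± 122.9 cm³ (male)
and 170.27 ± 89.25 cm³ (female); length 10 ± 2.3 and 8.7 ± 2.1 cm. The
published overall descriptive table's dispersion row is internally
consistent only as a standard error of the mean (its length entry times
$\sqrt{345}$ reproduces the sex-specific SDs), so single-slice predictor
SDs are taken as the published SEs scaled by $\sqrt{345}$; every report
this package writes prints both SD and SEM to avoid that ambiguity.

Per subject, (volume, length) are drawn from a bivariate lognormal whose
marginal means and SDs are moment-matched to the configured values. The
lognormal was chosen over a zero-truncated normal deliberately: at the
male coefficient of variation (0.55), zero-truncation plus feasibility
resampling inflates the realized mean about 4.5% above the configured
value, so a truncated-normal generator cannot reproduce the very moments
it is parameterized by; the matched lognormal is strictly positive and
reproduces them exactly, up to a small (≤ 5%, counted and logged)
rejection of draws whose volume is infeasible for their length. The
log-scale correlation defaults to 0.78, mirroring the strength of the
published length–volume association; the abdominal transverse diameter is
coupled to volume at 0.267 (its published standardized coefficient) and
all other predictors are independent of volume — the generator encodes
the study's qualitative conclusion (length dominates, one other predictor
weakly informative) without copying its covariance matrix, which is not
recoverable from the publication.

The phantom realizing each subject is a prolate spheroid: long semi-axis
= half the drawn length, short axes solved from $V=\tfrac43\pi a^2c$, so
the analytic volume equals the drawn volume exactly and the longest
extent equals the drawn length — one unambiguous coupling rule. Length
draws that cannot accommodate the drawn volume in a prolate shape are
resampled and counted. The L1-level and abdominal metrics are simulated
at the subject level (drawn values, not voxelized organs): the imaging
stages validate the volumetric chain, while the regression stage consumes
the full measurement vector.

**What the phantoms do not model.** Real MR contrast, bias fields,
breathing motion (spleens shrink during breath-holds), partial-volume
intensities at organ boundaries, lobulated hilum anatomy, and
operator variability beyond an optional 2% zero-mean between-rater noise.
Passing tests therefore demonstrate the correctness of the measurement
and statistics chain on known geometry, not segmentation robustness on
clinical images.

## Statistics

Rater pairs are averaged field-wise over available values (single-rater
subjects flagged, more than two raters an error). Splenomegaly
classification uses a strict `volume > threshold` rule with a required,
explicit threshold — no silent clinical cut-off is assumed, because the
modelled study never states the one behind its normal/high split.
Descriptives report mean, $n-1$ SD and SEM. The nine-predictor ordinary
least squares fit is computed from first principles — Householder QR for
the coefficients, $\hat\sigma^2 (X^\top X)^{-1}$ for the standard errors,
standardized $\beta_j = B_j s_{x_j}/s_y$, two-sided $t$ p-values on
$n-k-1$ degrees of freedom, $F=(R^2/k)/((1-R^2)/(n-k-1))$ — with listwise
deletion of incomplete cases (retained $n$ reported) and no
multiple-testing correction, matching the modelled analysis. The test
suite verifies the whole coefficient table against a brute-force
normal-equations oracle to $10^{-8}$ relative and the identity
$\beta = r$ in simple regression.

## Numerical and degenerate-input choices

- Empty masks: volume 0 with undefined CE; length and diameters error on
  empty input where a number would be meaningless.
- Interior zero-area sections are kept in the profile (legitimate
  observations); only leading/trailing zeros are trimmed, which provably
  changes neither $\hat V$ nor CE.
- CE scale invariance is exact in floating point for power-of-two scale
  factors and holds to $10^{-12}$ otherwise; the variance numerator is
  clamped at zero before the square root.
- Component-size ties in largest-component selection go to the component
  nearest slice 1 (then lowest in-slice coordinate), logged.
- DICOM geometry: an explicit centre-to-centre spacing tag wins over
  thickness + gap (it is definitionally $d$); absent both, spacing is
  inferred from slice positions; a single slice with no tags falls back to
  the thickness with a warning. Inter-slice spacing inconsistent beyond 1%
  is an error. All millimetre metadata convert to centimetres exactly once
  at the I/O boundary.

## Problem sizes used by the checks

The packaged checks run the unbiasedness property at 200 random offsets on
a mid-size ellipsoid, the CE-acceptability cohort at 100 phantoms at full
default resolution, and the 345-subject mean-recovery study at 0.3 cm
in-plane resolution (the acceptance script repeats it at the full 0.15 cm
default); these sizes give the stochastic assertions comfortable margins
while keeping a full run in tens of seconds on one core.

## Known limitations

Single-frame explicit-VR little-endian DICOM only (enough for the phantom
round-trip and any similarly plain series; no compressed transfer
syntaxes, enhanced multi-frame objects or oblique geometries). Phantoms
are star-shaped and smooth, kinder to the CE predictor than real lobulated
spleens — the package's mean CE (≈ 0.012 at default geometry) is
accordingly lower than values reported for patient data, and the CE
acceptability check is a bound, not a reproduction. The splenomegaly
threshold must come from the user; the regression assumes the usual OLS
error model and offers no robust alternatives.
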