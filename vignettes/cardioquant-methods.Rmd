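---
title: "Quantifying cardiac function from fluorescent heart-beating videos: models and design"
author: "cardioquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac function from fluorescent heart-beating videos: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioquant)
```

## Scope

`cardioquant` implements the computational core of an image-based
cardioprotective drug screen in larval zebrafish: (1) quantification of
cardiac function from fluorescence videos of the beating heart, (2)
Bliss-Independence synergy analysis of rescue-type endpoints, and (3)
Kaplan-Meier / log-rank survival comparison.  Because raw imaging data for
such screens are rarely deposited, the package ships a first-class
synthetic-data module with analytically known ground truth; every claim
the package makes about its own accuracy is verified against that ground
truth in the test suite.

## The cardiac function model

A transgenic line with fluorescent cardiomyocytes (e.g.
*Tg(cmlc2:mCherry)*) makes the ventricular chamber a bright, roughly
elliptical region in each frame.  For each frame the chamber is segmented
and summarized by its pixel-count area and by the side lengths $a$ (long)
and $b$ (short) of the rotated minimum-area rectangle around it.  With
end-diastolic (ED) and end-systolic (ES) frames identified per cycle, the
standard metrics are

$$\mathrm{FAC} = \frac{\mathrm{EDA} - \mathrm{ESA}}{\mathrm{EDA}} \times 100\%,
\qquad
\mathrm{FS} = \frac{\mathrm{EDa} - \mathrm{ESa}}{\mathrm{EDa}} \times 100\%,$$

$$\mathrm{Vol} = \frac{4\pi}{3}\,(a\,b^2), \qquad
\mathrm{SV} = \mathrm{ED.Vol} - \mathrm{ES.Vol}, \qquad
\mathrm{CO} = \mathrm{SV} \times \mathrm{BPM},$$

i.e. a prolate-spheroid volume model with the short axis as the two equal
semi-axes.  Metrics are averaged over at least four consecutive cycles.

### Design choices and their rationale

**ED/ES identification.**  In manual practice ED and ES frames are picked
from flow cues (last outflow / last inflow), which a segmentation mask
cannot see.  The package uses the standard surrogate: ED frames are local
maxima and ES frames local minima of the (lightly smoothed) chamber-area
trace.  Extrema are found on a run-length-compressed trace (rasterized
areas plateau near the extrema) and pruned by persistence: adjacent
extremum pairs closer than `minProminence` (default 10%) of the trace
amplitude are removed, so noise ripples never count as beats.  Trace ends
are eligible extrema, since a recording that starts at end-diastole would
otherwise lose its first cycle.

**Axis convention.**  The volume formula is printed in terms of axes $a,
b$ without stating whether they are semi- or full lengths.  Both are
implemented: `"semi"` (default; rectangle side / 2, the prolate-spheroid
convention) and `"literal"` (full side lengths fed to the formula
unchanged).  The two differ by a factor of exactly 8 in every volume;
FAC, FS, BPM and the synergy CI are invariant to the choice, which the
tests assert.

**Heart rate.**  The default estimator counts complete detected cycles
over the recording window (the manual beat-counting procedure), which is
exact whenever the video spans an integer number of beats.  The
alternative `median_interval` estimator (60 / median inter-ED interval) is
preferable for recordings truncated mid-cycle, but inherits the one-frame
localization jitter of the ED peaks: with an even number of intervals the
median can land between frame-grid points (e.g. 121.2 instead of 120 BPM
at 100 fps).

**Negative metrics.**  If segmentation fails on an extremum frame, FAC or
FS can come out negative.  Values are returned as computed, with a
`negative_fac`/`negative_fs` flag on the result, rather than clamped:
diagnosability over cosmetics.

## Segmentation and geometry

The default per-frame pipeline is Gaussian smoothing (sigma 1 px), Otsu
thresholding (a fixed threshold can be configured for noiseless work),
morphological closing (5 px disc), hole filling, and retention of the
largest 8-connected component, with size ties broken toward the image
centre (cropped heart videos centre the ventricle).  "Ventricular area"
is read as the chamber enclosed by the endocardial boundary: in `filled`
render mode the whole bright region, in `ring` mode the cavity enclosed by
the bright wall's inner contour.

The minimum-area rectangle is computed by rotating calipers over the
convex hull of the mask's pixel-corner points.  Because the minimal
rectangle provably has a side collinear with a hull edge, examining only
hull-edge directions is exact — the test suite confirms agreement with an
exhaustive 0.05-degree angle sweep to within 0.5% in box area on random
convex shapes.

### Numerical accuracy limits

Two discretization effects bound the achievable axis accuracy and are
worth knowing about:

* box side lengths quantize to roughly the pixel grid, so a side of
  $2b \approx 20$ px carries an irreducible ~5% uncertainty even for a
  perfect mask;
* the minimal box of a rasterized *smooth* shape (an ellipse, unlike a
  polygon) can snap its orientation toward the pixel grid at mild
  obliquity, trading up to ~1.7 px between the long and short side.

Chamber *area* (a pixel count) does not suffer from either effect and is
recovered to well under 2% for semi-axes of 10 px and up; axis-derived
quantities (FS, volumes) should be treated as having ~1 px per-side
uncertainty.  FAC — the primary contractility readout — is area-based and
unaffected.  In `ring` mode the cavity area is additionally biased low by
roughly the point-spread-function width along the wall's inner contour
(~5-7% at the default geometry); filled mode is the reference for the
accuracy figures above.

## The synthetic video generator

The generator renders an ellipse whose semi-axes follow
$a(t) = a_{ED}\,(1 - f_a\,s(t))$ with a periodic contraction waveform
$s(t)$, then applies Gaussian PSF blur, Poisson shot noise and Gaussian
read noise.  Choices:

* **Waveform**: an asymmetric raised cosine, $s = 0$ at end-diastole,
  reaching $s = 1$ after `systolicFraction` (default 0.4) of the cycle —
  systole faster than diastole, continuous, analytic, and integrable in
  closed form.  Frame 0 is end-diastole by convention.
* **Defaults** describe the reference recording: 128x128 px, 100 fps, 2 s,
  120 BPM, ED semi-axes (30, 18) px, contraction fraction
  $1 - \sqrt{0.6} \approx 0.225$ on both axes so the true FAC is exactly
  40%, background 0.1 and signal 1.0 intensity units.  Frame rate and
  pixel size are not dictated by the imaging protocol being emulated, so
  they are configurable; `noiseGaussianSd = 0.2` corresponds to a
  signal-to-noise ratio of about 5.
* **Determinism**: every random draw comes from a per-frame (or per-group)
  sub-stream derived from the top-level seed, so identical seeds give
  bit-identical output and partial regeneration is reproducible.
* **Distractors** are static bright blobs for testing the
  largest-component rule; moving distractors, optical sectioning and
  intracardiac flow are out of scope.

What passing tests on these videos do *not* show: robustness to
out-of-plane motion, photobleaching, wall-texture heterogeneity, or an
atrium overlapping the ventricle — real recordings should be spot-checked
against the per-cycle table.

## Bliss-Independence synergy

Per-animal endpoints are normalized into rescue effects $E \in [0, 1]$
(1 = restored to healthy-control level).  Two modes:

* `ratio_to_control` (default): $E_i = v_i / \overline{v}_{control}$,
  treating the control group as 100% effect; for `lower_better` endpoints
  (e.g. end-systolic diameters, where the disease model is *elevated*)
  the plain ratio cannot land in $[0,1]$, so the ratio is inverted,
  $E_i = \overline{v}_{control} / v_i$.
* `baseline_corrected`:
  $E_i = (v_i - \overline{v}_{model}) / (\overline{v}_{control} -
  \overline{v}_{model})$, which maps the disease-model mean to 0 and the
  control mean to 1 under either orientation.

How published analyses handle inverted endpoints is typically unstated;
both conventions are provided and neither is asserted as canonical.
Clipping to $[0,1]$ is off by default (transparency); out-of-range values
are flagged either way.

The additive (no-interaction) threshold is $E_{add} = E_A + E_B -
E_A E_B$ and the combination index $CI = E_{add} / E_{AB}$; $CI < 1$
means the observed combination beats independence.  Normalization is
per-animal — so the combination group provides a sample for a two-sided
one-sample t-test against the scalar $E_{add}$ — while $CI$ itself uses
group means.  The verdict is `synergy` only when $CI < 1$ *and* the test
is significant with positive direction.  Note the calibration subtlety:
$E_{add}$ is itself estimated from the single-agent groups but treated as
a fixed constant by the test, which makes the false-synergy rate mildly
anticonservative (measured ~0.05-0.065 at $\alpha = 0.05$, n = 10 per
group, sd 0.05 — within the binomial band of the nominal rate).
Per-metric p-values are reported unadjusted by default, with an optional
Benjamini-Hochberg flag.

The cohort generator inverts the chosen normalization, so true rescue
effects are recovered exactly at zero noise, and builds the combination
group's true effect as $\min(1, \gamma E_{add})$: $\gamma = 1$ is exact
additivity, $\gamma > 1$ built-in synergy.

## Survival

Event times are exponential per group, observed on a 0.5 h inspection
grid up to 32 h: a death is recorded at the first check after it occurs
(times round *up* to the grid), and animals alive at the horizon are
right-censored there.  Kaplan-Meier estimation and the log-rank
(Mantel-Cox) test are delegated to the `survival` package behind the
package's own interface; the tests verify them against a hand-tabulated
product-limit computation and a from-scratch per-time 2x2 contingency
log-rank.  Ties from the coarse grid are handled by the standard
hypergeometric variance; the measured type-I error at n = 50 per group
stays within about one percentage point of nominal.

## Problem sizes used in verification

The test-suite and acceptance script run entirely on simulated data at
desk scale: 100 random convex shapes for the geometry oracle, 20
rendered ellipses for segmentation recovery, 21 two-second videos (one
noiseless, 20 at SNR 5) for end-to-end recovery, 200 cohorts per synergy
factor plus 1000 null cohorts for CI calibration, and 1000 equal-hazard
replicates for log-rank calibration.  These sizes give Monte-Carlo bands
comfortably tighter than the tolerances being checked.

## Known limitations

* Axis-derived quantities carry ~1 px per-side discretization uncertainty
  (see above); sub-pixel contour fitting is out of scope.
* ED/ES selection by area extrema cannot reproduce flow-based manual
  timing when the two disagree (e.g. isovolumetric phases).
* The ellipsoid volume model assumes a prolate chamber; no attempt is
  made to validate it against true 3-D geometry.
* Only two-group log-rank comparisons are provided; no Cox regression or
  multi-group trend tests.
* Bliss analysis covers single-dose designs; median-effect or
  dose-response-surface models are out of scope.
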