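---
title: "Measuring retinal vascular tortuosity and validating it against expert panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vascular tortuosity and validating it against expert panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinotort)
```

## The problem

Tortuosity — how much, and how often, a retinal blood vessel bends — is a
candidate biomarker for diabetic retinopathy and other vascular disease.
Clinicians grade it on subjective ordinal scales with substantial
inter- and intra-rater variability, which is exactly what makes an objective,
repeatable computational measurement attractive, and exactly what makes
validating such a measurement delicate: the reference standard is itself a
noisy panel of human raters. `retinotort` implements both halves of this
problem: the measurement (four reference tortuosity metrics on vessel
centerlines extracted from fundus-style images, integrated into a single
per-retina score) and the validation workbench (rater-agreement analytics
and ROC analysis of continuous scores against binary consensus labels),
together with synthetic generators that provide ground truth where no public
clinical data exists.

## The four metrics

All four operate on a vessel centerline, an ordered polyline with arc length
$L_c$ and chord length $L_x$ (the Euclidean distance between its endpoints).

**Arc-to-chord ratio (distance metric).**
$\tau_{AC} = L_c / L_x - 1$. Dimensionless; zero for a straight vessel;
invariant under rigid motion and uniform scaling. It sees *how far* a vessel
wanders but not *how often* it bends: a single large arc and a tight
multi-lobed wiggle of equal arc/chord ratio score the same.

**Constant-sign-curvature subdivision (tortuosity density).** The vessel is
split into $n$ maximal subsegments over which the signed curvature does not
change sign, and
$$\tau_{SC} = \frac{n-1}{L_c}\sum_{i=1}^{n}
  \left[\frac{L_{csi}}{L_{xsi}} - 1\right],$$
with $L_{csi}$, $L_{xsi}$ the arc and chord lengths of subsegment $i$. The
$n-1$ prefactor makes any single-convexity vessel score zero and makes the
measure grow with the number of convexity changes; the $1/L_c$ normalization
gives it units of 1/length, so it behaves as a tortuosity *density*
comparable across image scales. Some statements of this measure carry an
additional $1/n$ factor; this package implements the form above and exposes
no variant, because mixing conventions silently changes magnitudes.

**Integrated curvature.**
$\tau_{IC} = \left(\sum_j |k(j)|^p\right)^{1/p}$ over the interior points of
the resampled centerline, with
$k = (x'y'' - x''y')/(x'^2+y'^2)^{3/2}$ and integer $p \ge 1$ (default 1, the
simplest strictly positive choice; $p$ tunes how strongly isolated sharp
bends dominate). Unlike the other metrics it is not normalized by length:
for a fixed sampling step it grows with both curvature magnitude and vessel
extent.

**Chain-code curvature density.** The centerline is rasterized to an
8-connected pixel chain; each step takes one of eight direction codes, and
the per-point curvature $K(p_i, k)$ is estimated from the smoothed code-angle
sequence (below). With $n$ the number of constant-sign subsegments of that
profile,
$$\tau_{CC} = \frac{n-1}{n}\,\frac{1}{L_c}\sum_i \left|K(p_i, k)\right|.$$
Magnitudes are summed rather than signed values: on a balanced S-curve the
positive and negative lobes would otherwise cancel and null the measure,
contradicting the requirement that it grow with inflection count.

**Tree integration.** Per-vessel values combine into one score per retina by
arc-length-weighted additivity,
$\tau = \sum_i L_{ci}\tau_{ci} / \sum_i L_{ci}$, which always lies within the
range of the constituent values. Longer vessels carry proportionally more
weight.

```{r metrics-demo}
v <- make_vessel(vessel_spec("sinusoid", length = 200, amplitude = 15,
                             half_waves = 4, n_points = 400))
vessel_tortuosity(v)
```

## Numerical choices in the curvature estimators

The derivative formula for $k$ is exact on smooth curves but meaningless on
raw pixel chains, so the estimator (i) resamples the polyline to uniform
arc-length spacing (default 1 px), (ii) low-pass filters the coordinates
with a Gaussian (default sigma 2 px) using point-reflection padding, which
extrapolates the curve linearly through its endpoints so straight lines stay
exactly straight and endpoints are not dragged inward, and (iii) applies
central differences. The first and last two samples cannot support central
differences; they carry curvature 0 and are excluded from the
integrated-curvature sum. Smoothing a circle of radius $r$ shrinks its
apparent radius by a factor $\exp(-\sigma^2/2r^2)$ — negligible for
vessel-scale bends ($\sigma \ll r$) but the reason curvature tests on
unit-radius analytic curves use proportionally small sigma.

For the partition into constant-sign runs, samples with $|k|$ below
`zero_tol` (default 1e-4 per px) inherit the sign of the running segment, an
all-flat vessel is a single segment, and runs shorter than `min_run`
(default 5 samples) merge into their longer neighbour so that noise-driven
micro-inflections do not inflate $n$.

The chain-code estimator needed one design iteration worth recording. The
obvious estimator — a windowed mean of the raw turn angles — is useless in
practice: rasterizing a line of arbitrary slope produces a staircase whose
turn sequence alternates between $\pm\pi/4$ at a period of a few pixels, and
a short boxcar neither cancels the alternation nor leaves the genuine
curvature signal (often below 0.02 rad/point for gentle vessels)
distinguishable from it. The implemented estimator instead unwraps the code
angles into a continuous direction sequence, smooths it with two passes of a
width-`k` moving average (a triangular kernel; an even `k` exactly cancels
the alternating staircase component), and differences the smoothed
direction. `k = 1` applies no smoothing, so a single right-angle corner
scores exactly $\pi/2$ at the corner pixel. The default `k = 8` puts the
residual quantization floor near 0.01 rad/point on oblique straight lines —
such lines therefore score small but nonzero chain-code tortuosity, an
honest limitation of grid-based curvature (axis-aligned and 45-degree lines
score exactly zero). The partition of the chain-code profile uses
chain-specific tolerances (`zero_tol` 0.02 rad/point, above the residual
quantization dips; `min_run` $2k$) rather than the derivative-profile
defaults, which would fragment the profile into spurious runs.

## Vessel extraction

The image pipeline mirrors crease-based vessel extraction: vessels are
ridges/valleys — elongated extreme-intensity structures — of the (green
channel of the) fundus image.

1. **Ridge detection.** At each scale $\sigma$ the image is
   Gaussian-smoothed, the Hessian is estimated by finite differences and its
   entries regularized with a Gaussian of scale `rho` (a structure-tensor-
   style smoothing that stabilizes the eigen-directions along tubular
   structures); the valley response is the positive part of the largest
   Hessian eigenvalue, scale-normalized by $\sigma^2$, and the map is the
   pointwise maximum over scales. Default scales are 1.5-3 px, matched to
   vessels 2-5 px wide ($\sigma \approx$ half-width). The largest scale
   governs how far the response bleeds past vessel endpoints (about
   $2\sigma$), which is why the default stops at 3 px.
2. **Binarization and thinning.** Otsu's threshold on the nonzero responses
   (a parameter-free default; an explicit threshold can be configured),
   followed by
   Zhang-Suen thinning plus a cleanup pass that deletes connectivity-
   preserving pixels from any residual 2x2 block, so the skeleton is
   guaranteed at most 1 px wide.
3. **Spur pruning and tracing.** Thinning curved ribbons leaves short side
   branches; branches that run from an endpoint into a junction within
   `spur_len` (default 8 px) are deleted. Junctions are skeleton pixels with
   crossing number (0-to-1 transitions around the 8-neighbourhood) of three
   or more — the plain 8-neighbour count misclassifies the 4-connected
   staircase pixels that thinning emits on diagonals, which would shatter
   curved vessels into fragments. Removing junctions splits the skeleton
   into simple paths, each traced from its lexicographically smallest
   (y, x) endpoint for determinism.
4. **Smoothing.** Traced centerlines get a moving-average polish
   (default window 9 points), chosen to cancel the ~0.4% arc-length
   inflation that the residual pixel staircase adds to every traced path;
   without it the arc-to-chord ratio of extracted vessels is biased upward.

Segments shorter than `min_points` (default 10) are excluded from tree
totals and reported as dropped.

## Synthetic data: what it emulates and what it does not

`make_vessel()` samples parametric centerlines (lines, circular arcs,
sinusoids, piecewise-sine multi-inflection curves) annotated with their
closed-form arc-to-chord tortuosity — for an arc of angle $\theta$,
$\theta/(2\sin(\theta/2)) - 1$; for sinusoids, adaptive quadrature of the
arc-length integral — and their interior inflection count.
`render_phantom()` draws them as dark constant-width ribbons with round caps
on a bright background (distance-to-centerline thresholding) plus optional
seeded Gaussian noise, and refuses layouts where distinct vessels come
closer than twice the width unless crossings are requested.
`simulate_panel()` draws true ordinal grades from a prior (default uniform
over the four grades, mirroring a balanced study design) and per-rater
reports from row-stochastic confusion matrices, independently per round;
`expected_kappa()` provides the closed-form agreement such a pair of raters
attains in the population, which the simulation must recover.

These phantoms validate the geometry: they do not attempt photorealism. No
optic disc, no lesions, no illumination gradients, no vessel-width
variation, no central reflex. Passing the extraction benchmark therefore
demonstrates correctness of the ridge/thinning/tracing/measurement chain on
clean tubular structures, not clinical-grade segmentation performance on
real fundus photographs.

Two quantitative limitations of the extraction benchmark are worth stating
precisely. First, crease-based extraction erodes vessel endpoints by roughly
$2\sigma_{max}$ (about 4 px at the default scales): for a circular arc the
arc-to-chord tortuosity then drops by approximately $4e/L$ relative (erosion
$e$ per end, length $L$), about 6% for a 260-px arc — which is why the
recovery benchmark uses lines and sinusoids, whose arc-to-chord ratio is far
less endpoint-sensitive, and why per-vessel agreement within 5% of the
analytic annotation should not be expected for short high-arc vessels.
Second, straight vessels have analytic tortuosity exactly zero, so their
recovery is asserted as a small absolute bound (measured arc-to-chord
tortuosity below 0.01) rather than a relative one.

The benchmark sizes used throughout the tests and the acceptance script —
300x300 phantoms with five vessels of 240-260 px, 10-image study bundles,
2000-image rating panels — were chosen as the smallest sizes at which the
statistical checks have comfortable margins, and they run in seconds.

## The validation workbench

The rating analytics operate on long-format tables (image, rater, round,
grade). The four-grade scale (none/mild/moderate/severe) supports two
clinically motivated binary groupings: tortuous-vs-non (0 | 1-3) and
asymptomatic-vs-symptomatic (0-1 | 2-3), the latter reflecting that mild
tortuosity carries no treatment need while moderate and severe can.
Cohen's kappa is computed between every rater/round pair — cross-round
pairs give the intra-rater agreement — and against majority-vote vectors
per round and pooled across rounds (the pooled vote counts every
expert-round vote, so five experts over two rounds contribute ten votes per
image). Exact vote ties resolve to the higher (more severe) grade, the
clinically conservative choice, and are flagged. Degenerate kappa (both
raters constant and identical, chance agreement 1) is reported as an
undefined flag, never coerced to a number. The printed interpretation bands
have a gap between 0.80 and 0.81; the package closes it with half-open
intervals [0, 0.20], (0.20, 0.40], (0.40, 0.60], (0.60, 0.80], (0.80, 1],
and labels negative values "less than chance".

Consensus percentages generalize "full / four / at least three coincidences"
among five raters to R raters via modal-count thresholds R, R-1, R-2; an
`exactly` flag switches the middle figure from "at least R-1" to
"exactly R-1", since prose descriptions of such figures are ambiguous.

ROC analysis treats higher scores as predicting the symptomatic class (the
direction is a convention; the package fixes it rather than guessing
per-dataset). One operating point per distinct score value plus the two
trivial endpoints, AUC by the trapezoid rule; equal scores form a single
threshold, which makes the trapezoid AUC *exactly* the Mann-Whitney pair
probability with half-credit ties — the package ships both computations and
its tests require exact agreement, so the two routes guard each other.
A binary expert prediction yields a single ROC point (sensitivity,
specificity) instead of a curve.

The bundled data are the *marginal* grade counts of a five-expert study of
60 fundus images from diabetic patients (two individual rounds, majority
votes, and a consensus round). The per-image labels behind those marginals
were never published, so per-image statistics of that study — its kappa
matrix, its expert ROC points — cannot be reproduced; the package instead
verifies what the marginals do pin down (grouping consistency, dataset-size
conservation) and validates the agreement/ROC machinery on simulated panels
with known ground truth.

## Reproducibility

Every generator takes an explicit seed; rendering and simulation are
bit-exact per seed, and `run_study()` regenerates its report bundle
bit-identically from identical inputs (numbers serialized at six significant
digits; no timestamps in the report). Deterministic tie-breaks — lexicographic
trace ordering, the higher-grade vote rule, grouped-tie ROC thresholds — are
chosen so that permuting input order changes no reported statistic.

## Known limitations

- Chain-code tortuosity has a quantization floor (~0.01/px) on oblique
  straight vessels and is invariant only under grid-preserving rigid
  motions; the derivative-based metrics are invariant under arbitrary rigid
  motion to numerical precision.
- The integrated-curvature metric depends on the resampling step (it sums
  per-sample curvature magnitudes); comparisons are only meaningful at a
  fixed step.
- Endpoint erosion biases arc-to-chord tortuosity of short, strongly curved
  vessels downward (see above).
- The extraction pipeline targets clean phantom imagery; real fundus images
  would at minimum need illumination correction and scale ranges matched to
  the vessel calibers present.
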