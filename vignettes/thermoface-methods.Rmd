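---
title: "Methods: thermal facial image analysis of emotion-evoked responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal facial image analysis of emotion-evoked responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`thermoface` implements an analysis protocol for infrared thermal facial
image (ITFI) sequences recorded while a subject watches a timed series of
emotion-evoking pictures. The scientific question the protocol serves is
whether the *amplitude* of emotion-locked facial temperature responses
differs between two clinical severity groups ("moderately ill" vs
"markedly ill"), and whether those amplitudes classify individual subjects.

The pipeline has five stages:

1. **Stimulation schedule** — a 225 s film of nine 15 s picture segments
   (three emotion types: HVLA, LVLA, LVHA — high/low valence crossed with
   low/high arousal), each segment followed by a 10 s rest break.
2. **Registration** — binocular center-of-mass pre-alignment to build a
   fixed reference image, then two-stage genetic-algorithm (GA) affine
   registration of every frame, compensating small spontaneous head motion.
3. **ROI features** — per-frame mean temperature of five facial regions
   (forehead, nose, mouth, left/right cheek), then stimulation-locked
   temperature-change features per emotion type (48 per ROI × emotion).
4. **Statistics** — per ROI × emotion block: PCA to 9 components and a
   two-group MANOVA via Wilks' Λ.
5. **Classification** — cross-validated SVMs (linear, quadratic, cubic,
   medium-Gaussian kernels) on 8–12 retained components.

Because no patient recordings are distributed, the package ships a
synthetic thermal-face phantom with known ground truth; every stage is
validated by parameter recovery and statistical calibration on that
phantom. Passing these checks demonstrates internal correctness of the
pipeline, not clinical validity on real faces (see *Limitations*).

# Stimulation schedule and frame windows

The default schedule is a repeating HVLA → LVLA → LVHA cycle (three
cycles), every 15 s segment followed by a 10 s break: 9 × 15 + 9 × 10 =
225 s, i.e. 450 frames at the camera's 2 frames/s. Each segment shows five
pictures of 3 s. The order of emotions within a cycle is not dictated by
the protocol contracts (total duration, counts, durations); it is
configurable, and the downstream statistics only depend on correct
windowing.

**Why 48 features per emotion?** Each emotion owns 3 × 15 s = 90 frames,
yet the feature contract is 48 per emotion. The only uniform per-segment
window reproducing 48 is 16 frames (8 s) per segment: 3 × 16 = 48. The
default window policy therefore takes the first 16 frames of each of an
emotion's three segments; offset and length are configurable
(`window_policy()`). An 8 s response window is also physiologically
sensible: with the response time constant below, ~80% of the asymptotic
response is reached within 8 s.

**Rest ("no stimulus") features.** The same policy is applied to the first
three rest breaks, producing a 48-feature rest block that is PCA-reducible
to 9 like the emotion blocks. Rest windows necessarily contain the decay
of the preceding segment's response; this carry-over is real (and the
rest block is routinely significant when any forehead effect exists), so
the rest block should be read as a post-stimulation reference, not as a
pure null.

**Baseline rule.** Features are temperature *changes*: each window is
expressed relative to the mean of the final 3 s of the event immediately
preceding its segment (the first event uses the sequence's first 3 s).
Per-segment baselining removes slow sensor drift almost completely —
residual drift within an 8 s window at the default 0.1 °C/min is
< 0.015 °C. Alternatives (`"global"`, `"none"`) are provided.

# The synthetic phantom

`phantom_config()` describes a 320 × 240 temperature field in °C:

* an ambient background at 27 °C (the acquisition protocol keeps the room
  at 26–28 °C);
* an elliptic face at 33.5 °C with rectangular ROI plateaus
  (forehead +1.0, nose −0.5, mouth +0.5, left cheek +0.3, right cheek
  +0.6 °C);
* two cool circular eye regions (−3.5 °C, radius 8 px) giving the
  high-contrast structures the binocular pre-alignment needs.

The right cheek is deliberately 0.3 °C warmer than the left. A lateral
asymmetry is required for mirror ("flip") detection to be decidable at
all — a left/right-symmetric face gives no information about acquisition
mirroring — and facial temperature lateralization is a reported phenomenon
in this literature.

**Response kinetics.** Each ROI × emotion cell has an asymptotic response
amplitude (°C). During a segment of emotion *e* the ROI's response rises
exponentially toward the amplitude with time constant τ = 5 s (first-order
kinetics); during other segments and breaks it decays toward 0 with the
same τ. The trajectory is linear in the amplitudes, so a subject's ROI
series is `baseline + Σₑ aₑ · shapeₑ(t)`, with `shapeₑ` the closed-form
unit response (`emotion_shapes()`). Default group amplitudes encode the
qualitative group-difference structure under study: forehead differences
under all three emotions (largest under LVHA), nose differences under all
three, right-cheek difference under HVLA; mouth and left cheek respond
equally in both groups. Between-subject amplitude heterogeneity is
N(0, 0.1 °C) by default. The amplitudes are free parameters of the
phantom — no real-data effect sizes in °C are available to match.

**Noise model.** Three stochastic components, each configurable:

* pixel-wise i.i.d. Gaussian sensor noise, sd 0.05 °C;
* per-frame, per-ROI *physiological fluctuation*, sd 0.05 °C. Skin
  perfusion fluctuates on this scale and is spatially coherent within a
  region, so — unlike pixel noise, which the ROI mean averages down by
  √n_pixels — it survives ROI averaging. Without this component the
  ROI-mean noise floor would be ~0.001 °C and *any* trace of a group
  difference (e.g. the decay tail of a response carried into a
  neighbouring window) would reach extreme significance, because
  multivariate group separation is invariant to the scale of the carrying
  signal. The fluctuation term is what gives the feature blocks a
  realistic signal-to-noise ordering;
* linear sensor drift, 0.1 °C/min.

**Head motion.** Independent per-frame rigid-plus-scale jitter:
translation sd 2 px per axis, rotation sd 1°, isotropic scale sd 0.5%.
Frames are warped by the jitter transform (bilinear, pull convention) and
the exact transforms are returned as ground truth.

**Series-level twin.** `simulate_cohort_series()` emits per-ROI mean
series directly from the closed form, with ROI-mean sensor noise
`noise_sd / √n_pixels` plus the ROI fluctuation — the distribution of ROI
means of registered, unjittered image sequences. A test verifies exact
agreement with the image path when all noise is off. Calibration studies
(hundreds of cohorts) use this path; rendering full image cohorts at that
scale would be pointless for statistics that only see ROI means.

**Study conditions.** Cohorts default to 18 moderate + 17 marked subjects,
the sizes of the clinical study this protocol models. The type-I
calibration uses the all-zero amplitude array (`null_amplitudes()`). The
signal-recovery experiment uses `signal_recovery_config()`: a single
planted forehead-LVHA amplitude gap of 0.25 °C (moderate 0.15, marked
0.40 °C — within the 0.1–0.5 °C range of emotion-evoked facial temperature
changes reported in thermography) over between-subject sd 0.05 °C, zero
amplitudes elsewhere. That standardized amplitude separation (5) yields
~90% cross-validated accuracy, consistent with the upper range reported
for the clinical cohort, and makes the planted cell the most significant
MANOVA cell in the clear majority of cohorts. Its only competitor is ever
the forehead rest block, which inherits the planted effect through
post-stimulation decay — the same phenomenon the clinical study observed.

# Registration

**Fixed image.** The reference is built from the first frame: locate the
binocular centers, optionally mirror-correct, and translate the binocular
midpoint to a canonical position (default: image center column, 40% of
the image height). Mirror detection compares the mean face temperature of
the two lateral halves about the binocular midline against a canonical
warm side; it is only decidable for faces with lateral asymmetry.

**Eye localization.** Face mask = pixels warmer than the frame median by
1 °C (the background dominates the field of view, so the frame median sits
at ambient). Within the face interior — the mask eroded by 2 px, which
excludes the boundary ring where resampled frames blend skin and
background temperatures — pixels colder than the face median by 2 °C are
thresholded; speckle components under 10 px are discarded; exactly two
components must remain, else localization fails loudly. Centroids are
weighted by coldness depth, giving sub-pixel precision.

**Two-stage GA.** The fitness is the negative mean absolute temperature
difference (MAD) over the fixed image's face mask — robust, and in °C so
fitness values are interpretable as overlap error. Stage 1 searches
translation and rotation over wide bounds (|tx|, |ty| ≤ 15 px, |θ| ≤ 10°)
with scales fixed at 1; stage 2 searches all six affine parameters within
narrow bounds centered on the stage-1 optimum (±3 px, ±2°, scales
1 ± 0.05, shear ±0.05). GA settings: population 50, 60 generations per
stage, tournament selection (k = 3), uniform crossover (rate 0.8),
Gaussian mutation (rate 0.1, sd 10% of bound width), elitism 2 — all
configurable via `ga_config()`. Elitism makes the per-generation best
fitness non-decreasing, which is asserted by tests. The fitness is
evaluated on at most 8000 evenly spaced mask pixels (metric subsampling,
the standard speed device of intensity-based registration); reported
overlap errors always use the full mask. With these defaults a planted
jitter of the phantom's magnitude is recovered to ~0.1 px and ~0.05°
(median), about 5–6 s per frame on one CPU.

Numerical conventions: 0-based pixel coordinates, x = column, y = row;
transforms act about the image center in pull convention (the output
pixel takes the input value at the transformed location); linear part
composed as `R(θ) · diag(sx, sy) · shear`; bilinear interpolation with a
fill temperature outside the domain; identity parameters return the input
bit-exactly. Registering a frame warped by transform *P* recovers *P*⁻¹.

# Statistics

**PCA.** Each ROI × emotion block (35 subjects × 48 features) is centered
(not variance-scaled — all features share °C) and reduced to k = 9
principal-component scores. The PCA is fit across subjects *per block*:
that is the only scope under which 48 → 9 produces a 35 × 9 MANOVA input
per cell. Component signs follow the largest-loading-positive convention
so results are reproducible across platforms.

**MANOVA.** Wilks' Λ = det(E) / det(E + H), with E and H the within- and
between-group SSCP matrices. For two groups the transform
F = ((1 − Λ)/Λ) · ((N − k − 1)/k) on (k, N − k − 1) degrees of freedom is
exact — it equals Hotelling's T² up to the standard constant — so no
large-sample approximation is involved; with N = 35 and k = 9 the degrees
of freedom are (9, 25). Determinants are computed via Cholesky
log-determinants; a singular E raises an error advising a smaller k rather
than returning a misleading statistic. The package's implementation is
cross-checked in the tests against an independently coded Hotelling T²
oracle (agreement to 1e-10) and against `stats::manova`. Raw p-values with
0.05/0.01/0.001 stars are reported by default; Bonferroni correction is
available as an option but is not applied by default, matching the
reporting convention the protocol follows.

**More than two groups** are out of scope: the exact two-group transform
is the point, and general Wilks F approximations are deliberately not
implemented.

# Classification

Stratified k-fold cross-validation (default 5 folds — the customary
default of the point-and-click tool the protocol names; configurable) of a
C-SVM with unit box constraint. Kernel presets: linear; quadratic and
cubic polynomials (coef0 = 1); "medium Gaussian", a radial basis with
length scale √k, i.e. γ = 1/k for k features. Features are standardized
with training-fold statistics only. Accuracy is the percentage of all
subjects classified correctly across held-out folds, hence always a
multiple of 100/N.

By default the PCA is fit once on the full block *before*
cross-validation, mirroring the sequential reduce-then-classify protocol
this package models; that leaks the unlabeled feature geometry of test
subjects into the reduction. A leakage-safe mode (`pca_in_cv = TRUE`)
refits the PCA inside every training fold and is the methodologically
preferred option; on strongly separated synthetic cohorts the two agree.

# Problem sizes used in validation

The test-suite and acceptance-script experiments use sizes chosen to make
each check statistically meaningful at desk scale: 20 planted-jitter
frames for registration recovery (median error thresholds 0.5 px / 0.5°),
100 random instances for the MANOVA-oracle agreement, 200 simulated null
cohorts (4000 cells) for type-I calibration against the [0.03, 0.07]
band, and 50 signal cohorts for planted-effect recovery and the SVM
accuracy comparison against permuted labels. Full-image runs in the tests
use short schedules and small cohorts; the statistical experiments use the
series-level twin.

# Limitations

* The phantom is geometric (ellipse, rectangles, disks), with sharp region
  boundaries and spatially constant responses per ROI; it does not model
  anatomy, perspiration, breathing artefacts, glasses, hair, non-rigid
  expression motion, or camera non-uniformity. Passing recovery tests on
  the phantom shows the pipeline is internally correct, not that it is
  robust to all real acquisition effects.
* Real effect sizes in °C are unknown; synthetic amplitudes are free
  parameters, so real-cohort F values and accuracies cannot be reproduced,
  only the structure of the analysis.
* Mirror correction requires a lateral temperature asymmetry.
* ROI geometry (eye-anchored proportional rectangles) is an invented
  default; deployments should override it via the ROI JSON file.
* The exact windowing that produces 48 features per emotion is a
  reconstruction (8 s per segment); it is configurable because the
  protocol's own rule is not stated.
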