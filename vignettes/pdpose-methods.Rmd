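---
title: "Pose-based PD phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pose-based PD phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdpose)
```

## The problem

Parkinson's disease (PD) models in mice are conventionally assessed with
coarse behavioural assays (beam walking, rotarod) that are insensitive to
early or mild phenotypes. An alternative is to track the animal's full 3D
pose — 9 body nodes (nose, neck, chest, both hands, both feet, anus, tail
tip) at 30 Hz in an open field — and to quantify disease from the kinematics
directly. `pdpose` implements that computation end to end: motion
segmentation, feature engineering, a clip-level disease classifier with an
animal-level severity score, spectro-temporal tremor signatures, event-level
analyses (turning, rearing, gait, axial bending, foot placement), and the
longitudinal and treatment-response statistics built on top.

Because in-vivo recordings are large and not redistributable, the package
ships a parametric synthetic pose generator that emulates realistic
recording conditions and provides exact ground truth for every downstream
stage.

## Motion segmentation

Chest 3D speed is thresholded at 1.5 cm/s; a trailing 100-frame window is
*Moving* when more than 80% of its frames exceed the threshold; moving
*episodes* are maximal unions of overlapping qualifying windows. Episodes
are tiled into fixed-length clips (60 frames = 2 s for the kinematic table,
120 frames = 4 s for spectro-temporal and event analyses), dropping the
remainder. Two consequences of the window-union rule worth knowing:

* an episode can extend up to `window * (1 - frac)` = 20 frames into the
  surrounding rest on either side, and
* rest gaps shorter than 20 frames merge adjacent episodes.

The inter-episode *interval* is the gap between episode bounds; for the
first episode it is the time since session start, which keeps the feature
defined for every episode. Window sums are trailing, not centred.

## The 340-feature clip table

Per frame the registry holds 83 signals: 27 node speeds (each node in 1D
vertical, 2D horizontal and 3D space; the displacement over `(t-1, t]`
scaled by the sampling rate, frame 0 padded from frame 1), 7 angles, 14
node-pair distances, 8 absolute angle differences and the 27 raw
coordinates. Per clip each signal is summarised by min, max, mean and
standard deviation (n−1), giving 332 columns; 8 episode-level temporal
parameters (duration, interval, clip count, onset, chest path length, mean
speed, rest ratio, ordinal) complete the 340. The angle and distance sets
are pinned in `kin_angle_defs()` / `kin_dist_defs()`; they cover every
named headline feature (hands 3D distance, feet 2D distance, body 2D
length, body angle, and so on) and are configurable if a different
inventory must be reconciled.

Outliers are handled by quantile trimming (0.01/0.99 per feature within
group). Trim bounds are estimated once from the incoming table and stored
on the result, so re-applying the same trim is a no-op. This is deliberate:
with re-estimated quantiles, strict trimming is not idempotent (each pass
shaves the new tails), and freezing the bounds is the only semantics under
which "trim twice = trim once" holds exactly.

## Spectro-temporal descriptors

Six operators are implemented from their closed-form definitions and
checked against brute-force oracles:

* **Ricker CWT** at integer widths 1–9 (centred kernel of
  `min(10a+1, T)` samples, same-length convolution per scale).
* **Wavelet entropy**: Shannon entropy of the per-scale energy distribution
  (sum of absolute coefficients over time, normalised); bounded by
  `log(9) ≈ 2.197`. Zero-energy signals are defined as 0.
* **Fundamental frequency**: mean-removed DFT; spectral peaks are bins
  above 30% of the maximum magnitude; the fundamental is the lowest
  strictly positive peak. On a 4-s clip the frequency grid is 0.25 Hz.
* **Wavelet std at width 5**: the n−1 standard deviation of the scale-5
  coefficients.
* **PSD bandwidth**: the signal is normalised by its standard deviation, a
  single-segment Welch density (periodic Hann window, mean detrend) is
  computed, and the bandwidth is the distance between the forward and
  reversed cumulative-power 95% crossings — near 0 for a pure tone, near
  0.9 of Nyquist for white noise. Of the two common conventions for
  indexing the bounds, this package follows the established
  feature-library semantics, which yields these orderings.
* **Zero-crossing count** (`sgn(0) = 0`, so steps through an exact zero do
  not count) and **zero-lag autocorrelation** (signal energy).

These operators plus min/max/mean/std are applied to 8 pinned core signals
(chest/neck 3D velocity and acceleration, tail angle, tip 3D velocity,
hands 3D distance, feet 2D distance) over long clips, yielding an 88-column
table; larger expansions depend on a particular external library
configuration, so the registry product is logged rather than forced to a
constant.

## Classification and severity scores

Clips from the two groups are balanced by downsampling the majority class,
split 7:3 stratified, filtered (near-zero variance, then greedy removal of
|r| > 0.95 collinear duplicates), ranked by mean absolute additive (SHAP)
attribution from a preliminary boosted ensemble, and the top 30 features
train the gradient-boosted clip classifier. Validation metrics (accuracy,
precision, recall, F1, Cohen's kappa, MCC) are stored on the fitted
`pd_model`. The animal-level **APS** is the percentage of a mouse's clips
classified PD, binned [0,25) non-PD, [25,75) mild, 75+ severe (the upper
boundary is closed on the severe side).

The per-stride gait classifier works identically but with a 6:4 split, 20
selected features and an extremely-randomised-trees ensemble (no bootstrap,
full sample, random split points); the **PD gait score** is the percentage
of PD-characteristic steps. Tree ensembles tolerate missing feature values
natively in the boosted model; the randomised forest imputes training-column
medians, which are stored on the model.

Additive attributions are exact per-tree (TreeSHAP) values in log-odds; the
base value plus the attributions reproduces the model margin. The ensembles
evaluate in single precision, so the additivity residual is asserted
relative to the margin scale (1e-6 relative).

## Event-level analyses

**Turning.** The hindbody heading (anus-to-chest, horizontal) is
differenced at a lag of two frames, wrapped to (−180, 180]; changes of at
least 90° are zeroed as noise; a 5-frame trailing rolling mean (with
partial start-up windows) smooths the series; frames are categorised
left/right/none by sign where the smoothed rate exceeds 0.5°/frame, and
maximal same-category runs of ≥ 5 frames are events. The cumulative heading
change counts the full two-frame lag at onset and half the smoothed lag
difference per subsequent frame, which makes the constant-rotation case
integrate exactly to the true heading change. The rate threshold and
minimum run length are package choices; they suppress jitter while
keeping slow turns.

**Rearing** is annotation-driven (rearing is annotated manually in
practice; the generator supplies exact annotations): 11 features
from the chest's vertical excursion — up/down displacement, three
durations, and mean/max/std of signed vertical velocity per phase.

**Gait.** A foot strike is a swing-to-stance transition; strides span
consecutive strikes of one foot; strides overlapping rearing are removed.
The 28-descriptor registry covers timing, amplitude, foot dynamics,
interlimb coordination (including contralateral leg-angle correlation and
left-right phase lag), posture and locomotor context; the registry is
pinned here and configurable for reconciliation with other inventories.

**Axial bending**: the interior angle at the hind-foot midpoint between
vectors to nose and anus; frames below 75° are flagged; a 60-frame rolling
mean ≥ 0.7 defines bending episodes, extended 60 frames backward and tiled
into 60-frame clips with mean angle. **Foot placement** maps hind feet into
the body frame (anus origin, +x toward the chest); the trailing signature
is the percentage of positions with negative body-frame x.

## Group statistics

Kernel density estimates use a Gaussian kernel with Scott's bandwidth
(`sd * n^(-1/5)`) on a 200-point grid spanning the data ± 3 bandwidths.
KL divergence interpolates the second density onto the first grid and
integrates `p log(p/q)` trapezoidally over points where both densities
exceed 1e-12 (the floor implements "computed only when both estimates are
available"). Longitudinal analysis draws 6 seeded sets of 150 clips per
week and tracks the divergence of each week from the week-0 baseline.

Task scores use the mean of the two best trials (shortest latencies for
beam walking, longest for rotarod) relative to baseline, with beam-walking
scores above 600% excluded; the tail-suspension score weights the three
abnormality classes 1:2:3, a class counting only when at least two
incidences each exceed 2 s.

Treatment-response evaluation runs three Welch comparisons per feature
(PD vs control, treated vs control, treated vs PD), each Holm–Sidak
corrected across the feature family, the family being one comparison
batch. The category rules are a
complete decision tree: not-affected features are `unaffected` unless the
treatment itself moved them off control (`treat_associated`); affected
features are `completely_treated` when indistinguishable from control,
`untreated` when indistinguishable from PD, `partially_treated` when all
three comparisons are significant and the treated mean lies strictly
between the PD and control means, and `treat_associated` otherwise. The
one combination the prose leaves open (unaffected in PD but shifted from
control after treatment without differing from PD) is assigned
`treat_associated`, keeping the assignment exhaustive and exclusive.

## The synthetic generator

The generator is a harmonic-plus-noise model: a smoothed random walk of the
body centre inside a 40 × 40 cm arena (heading wobble plus gentle steering
away from walls; heading frozen at rest), alternating rest/movement bouts,
left–right anti-phase limb oscillators whose cadence follows locomotion
speed (stride length fixed at 3 cm), a chest vertical oscillation band at
the phenotype frequency with a matching multiplicative speed surge (which
is what places the band's fundamental at the parameter value in the speed
and acceleration signals), rearing events as half-sine chest elevations
with parameterised peak vertical velocity, and parametric posture geometry
(body length, interior body angle, hand separation, stance width). Swing
phases are defined by the oscillator phase (swing = forward half-cycle), so
stride detection has an exact oracle; foot-trailing strides suppress the
swing lift entirely.

Preset anchors follow in-vivo reference ranges for this disease model:
control hands separation 2.5 cm (healthy range 2–3 cm) against 1.1 cm in
severe PD (0.5–1.7 cm); stance 2.8 vs 4.2 cm; body length 4.2 vs 5.0 cm
(straddling the 4.63 cm decision value); chest band 2.8 vs 6.0 Hz;
foot-trail probability 0.3 for severe PD. Where no reference value exists (bout
structure, speeds, noise levels, rearing dynamics) the defaults are chosen
once at what a rodent open-field literature reader would call realistic:
~3 bouts/min of ~8 s at ~6 cm/s for controls, fewer, longer, slower bouts
for PD (PD episodes last longer, matching the headline motion-duration
direction). `speed_complexity` — a multiplicative broadband roughness on
the bout speed profile — is an addition to the phenotype parameter set: it
carries the "less predictable" chest dynamics of healthy animals, which is
what separates the groups in wavelet entropy. Tracking noise is smoothed
(AR(1)) and small (0.1–0.15 mm), cleaner than a camera system would
deliver; it is chosen so the planted oscillation band, not sensor noise,
dominates the acceleration spectrum.

What the generator does **not** emulate: photorealistic marker error
structure (heavy-tailed, occlusion-correlated), genuine biomechanics
(masses, joint limits), behavioural syntax (grooming, sniffing bouts), or
inter-individual correlation structure beyond the per-session parameter
draws. Passing tests on synthetic cohorts therefore demonstrates that the
computation recovers what was planted under realistic magnitudes — not
that the classifier would reach the same accuracy on in-vivo recordings.
In particular the near-perfect synthetic classification accuracy reflects
the cleanly separated presets, and is read as "the pipeline can recover a
strong planted contrast" — a property check, not a claim about in-vivo
accuracy.

## Numerical choices and degenerate inputs

* Gaps in pose files: interior NA runs ≤ 5 frames are linearly
  interpolated; longer runs or boundary gaps reject the session (tracking
  dropout policy; the source workflow is silent).
* Degenerate geometry (coincident nodes for an angle, anus≈chest within
  1e-6 cm for the body frame or heading) masks the frame rather than
  erroring; masked frames are excluded from clip statistics.
* Constant signals: fundamental frequency is flagged undefined; PSD
  bandwidth is 0; wavelet entropy of a zero-energy signal is 0 (logged).
* Problem sizes: tests and the acceptance script use 5-minute sessions and
  10 mice per group — enough clips (~40 per session) for stable group
  statistics — and one full 20-minute session for the structural schema
  checks. TRE recovery uses 500 seeded replicates at n = 20 per group with
  3-sd effects.
* All randomness flows from explicit integer seeds; cohort generation is
  bit-reproducible.

## Known limitations

The 340-column inventory and the 28 gait descriptors are pinned
registries; both are configurable for exact reconciliation against other
inventories. The spectro-temporal expansion reports its registry product
rather than a fixed feature total. Cross-view ensembling, automatic
rearing/swing detection from raw pose, and the exploratory clustering and
curve-fitting analyses are out of scope.
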