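---
title: "Validating markerless ROM measurement: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating markerless ROM measurement: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Optical motion capture reports 3D marker positions in a laboratory frame
whose axes can be installed parallel to the subject's anatomical plane
normals. A monocular pose-estimation model reports 3D landmark positions in
a frame tied to the camera: rotate the camera and every coordinate changes,
though the joint angles do not. Comparing joint range of motion (ROM)
between the two systems therefore requires (i) a camera-invariant
coordinate construction, (ii) a common angle definition, and (iii) temporal
alignment of streams sampled at different rates with an unknown start
offset. `romval` implements all three plus the agreement statistics, and a
synthetic generator that makes each stage testable against exact ground
truth.

# The anatomical frame

Given the two shoulders and two hips of one frame, the frame is:

* **origin** — hip midpoint;
* **ŷ** (transverse-plane normal) — unit vector from shoulder midpoint to
  hip midpoint. It points caudally ("down" for an upright subject), which
  is also the 0° reference direction of the neutral-zero angle convention;
* **ẑ** (frontal-plane normal) — consensus-plane normal of the four torso
  points, re-orthogonalized against ŷ;
* **x̂** (sagittal-plane normal) — ŷ × ẑ (right-hand rule).

Assumptions: the four torso points are nearly coplanar and the shoulder and
hip midpoints are distinct; the subject's anterior side faces the camera to
within 90° of yaw (used only to pick the sign of ẑ, below). The frame is
built once, from the first frame in which all four torso landmarks are
visible, and held static for the acquisition — re-estimating it per frame
would let torso sway leak into the joint angles.

Three points were genuinely open and are our choices:

* **RANSAC parameters and degeneracy.** A consensus fit over four points is
  near-degenerate, so candidate planes are exact fits to point triples,
  enumerated exhaustively (four triples; random subsampling with a fixed
  seed only engages above `max_trials` combinations, i.e. for larger point
  sets). Inliers are points within `residual_threshold = 0.01` m; the
  winning inlier set is refit by total least squares (SVD). If no triple
  forms a consensus the fit falls back to TLS on all points. This is
  deterministic and, for coplanar torsos, equals the TLS plane.
* **Non-orthogonality.** The fitted ẑ and the measured ŷ are not exactly
  perpendicular on noisy data. ŷ is the more direct anatomical measurement
  (two midpoints), so ŷ is kept exact and ẑ is projected into its
  orthogonal complement and renormalized.
* **Sign of ẑ.** A plane normal has two signs, and the right-hand-rule x̂
  flips with it. The sign is chosen so that ẑ has positive dot product
  with an `anterior_hint` vector (default `c(0, 0, 1)`, correct for any
  camera looking at the subject's front within ±90° of yaw; configurable
  for other rigs).

The ground-truth stream does not get a fitted frame: its axes are assumed
parallel to the anatomical normals, and `apply_axis_convention()` just
remaps which laboratory axis is "down" and which is "anterior".

# Amplitude computation

Per frame, the exercise's body segment vector (e.g. shoulder→elbow for
shoulder abduction) and the reference direction are both projected onto the
plane of movement (frontal plane ⇔ suppress the ẑ component; sagittal ⇔
suppress x̂), and the amplitude is the unsigned angle between the
projections, `acos` clamped to [−1, 1], in [0°, 180°]. Choices:

* **Unsigned angles.** The neutral-zero ROM convention reports excursions
  from the zero position as magnitudes; flexion vs extension sign is not
  modeled, matching how validation tables report amplitudes.
* **Reference directions.** "Down" is +ŷ for every exercise except the
  squat, whose reference is the per-frame foot→knee vector; the dynamic
  reference is projected onto the movement plane exactly like the segment.
* **"Foot" means ankle.** The marker set's most distal marker is the
  lateral malleolus, so the squat and seated-knee configurations use the
  ankle landmark on both skeletons (the predicted skeleton's heel or toe
  would have no ground-truth counterpart). This is configurable per
  exercise config.
* **Degenerate frames.** A segment that collapses to zero length under
  projection (or a missing required landmark) yields a missing amplitude
  for that frame, not an error; downstream stages treat missing samples as
  gaps that break peak neighborhoods and are dropped from matched pairs.

Only right-side joints are evaluated; the eight configurations ship as a
built-in registry (`exercise_registry()`).

# Temporal alignment

The two streams run at 100 and 30 FPS and start at unknown relative times.
The five-step procedure: seconds from frame indices; peak detection;
coarse alignment by first peaks; nearest-time matching; Pearson-based
fine-tuning. Numerical choices that matter:

* **Peak detection** uses topographic prominence with a threshold of 0.2 ×
  the series range and a 1.0 s minimum separation — repetitions are
  seconds-scale and tens of degrees, so both defaults are far from the
  noise floor.
* **Quadratic peak-time refinement.** The raw argmax of a noisy, gently
  curved pulse apex can jitter by several sample periods, and the alignment
  offset is a difference of peak times. Each peak time is therefore refined
  as the vertex of a least-squares parabola fit over ±0.5 s around the
  argmax (clamped to the window; disabled with `refine_window_s = 0`). On
  noiseless data the refinement is exact to well under a sample period; on
  noisy data it reduces peak-time jitter enough for the offset-recovery
  guarantee below. Peak *amplitudes* remain raw sample maxima.
* **Offset snapping and the match tolerance.** At 100 vs 30 FPS the two
  time grids coincide only on a 10 Hz subgrid. Matching every predicted
  sample to its nearest ground-truth sample (≤ 5 ms away) would pair
  samples up to 3.33 ms apart in time — harmless for noisy statistics but
  fatal for exactness: a 3.33 ms mismatch on a 24°/s flank is a 0.08°
  error, visible at the 1e-6 tolerances the synthetic world is supposed to
  meet. `match_samples()` therefore snaps the applied offset onto the
  ground-truth sample grid and keeps, by default (`tolerance_s = 1/600`),
  only pairs within 1.67 ms — exactly the simultaneous 10 Hz subset when
  grids align, and always a non-empty ~1/3 subset for arbitrary offsets.
  Passing `tolerance_s = 0.005` restores the keep-everything
  nearest-neighbour behaviour.
* **Fine-tuning search.** Candidate offsets are differences of the first
  three peaks of each stream (≤ 9 re-scorings, deterministic); each is
  scored by the Pearson r of its matched samples; ties break toward the
  coarse offset. The coarse pairing is among the candidates, so the
  fine-tuned r can never be worse — this also rescues alignments where one
  stream has a spurious early peak (familiarization) or where the predicted
  recording starts after the first repetition.
* **Segmentation** runs on the aligned ground-truth series (the less noisy
  driver); peaks below 0.6 × the median peak amplitude are discarded as
  resting wobble/incomplete trials, and each window extends to the nearest
  strict local minimum on each side (strictness stops the walk at the edge
  of a resting plateau, keeping windows non-overlapping).

# Agreement metrics

MAE and MAPE, Pearson r with a two-sided p-value, cosine similarity on raw
(non-centered) vectors — deliberately magnitude-insensitive, unlike
Pearson — and an OLS regression with x = predicted, y = ground truth (the
direction that maps model output into expected values). Two scoping
decisions:

* **The 1° threshold filters on ground truth only** (`|y| < 1°`): only the
  denominator of MAPE can blow up, and that denominator is the ground
  truth.
* **The threshold defines the motion-amplitude dataset.** All motion-block
  metrics (including MAE and the regression), and the reported `n`, are
  computed on the surviving pairs; `n_excluded_by_threshold` records the
  rest. Peak amplitudes are far from zero, so the filter is inert there.
* **Pooling.** Metrics pool all samples of an exercise into one vector pair
  rather than averaging per-subject coefficients, matching evaluation
  "across all participants"; per-subject analyses can be run by calling
  `evaluate_exercise()` per acquisition.

# The synthetic world

`angle_profile()` drives each acquisition with raised-cosine pulses
(0 → peak → 0) — smooth, symmetric, zero-velocity at rest, a reasonable
idealization of a guided exercise repetition. The stated world: 2 sets × 7
repetitions, 10 s rest between sets, 3 s per repetition, 90° nominal peak
with 3° rep-to-rep jitter; ground truth at 100 FPS on the 6-marker skeleton,
prediction at 30 FPS on the 33-landmark skeleton; frontal-plane exercises
rendered at 0° camera yaw and sagittal ones at 35° (the occlusion-minimizing
camera placement); 5 mm landmark noise and a 2 s start offset in the default
study configuration. The body template (upper arm 0.30 m, forearm 0.27 m,
thigh 0.42 m, shank 0.40 m, torso 0.35 × 0.50 m, hips 0.20 m apart) is
plausible adult anthropometry; amplitudes are scale-invariant, so it only
sets the gear ratio between positional noise and angular error.

Two generator decisions deserve justification:

* **Error channels are separated.** Camera/depth error is modeled as
  isotropic Gaussian *position* noise (to exercise the full geometric
  pipeline) plus optional Gaussian *angle* noise (to state closed-form
  expectations like E|N(0, σ)| = σ√(2/π)); systematic scaling/shift error
  is a *linear amplitude map*. These are the two qualitatively different
  error modes a validation study reasons about.
* **The linear distortion is injected on the ground-truth side** — the
  ground truth plays `slope × profile + intercept` while the prediction
  plays the raw profile — so that `gt = slope · pred + intercept` holds
  identically for every sample. Injecting it on the predicted side as
  `(profile − intercept)/slope` would demand negative predicted angles
  whenever the profile drops below the intercept; an unsigned amplitude
  measurement folds those back into [0°, 180°] and bends the relation near
  zero, making exact recovery of the injected slope and intercept
  impossible in principle. With positive intercepts the relation is exact
  everywhere and the pipeline's regression must return the injected
  coefficients to machine precision — which the acceptance suite asserts.

What the generator does **not** emulate: soft-tissue artifact, marker
occlusion/dropout patterns, autocorrelated or pose-dependent estimation
error, multi-joint coordination beyond the moving limb, left/right
asymmetry, or nonlinear (e.g. cubic) amplitude relations. A green test
therefore establishes that the *pipeline* is correct and camera-invariant in
its stated world — not that any particular pose-estimation model meets a
clinical accuracy bar. Real-data conclusions require running the files mode
on real exports.

# Determinism and tolerances

All randomness flows from explicit integer seeds (the study runner derives
per-exercise seeds from one top-level seed); RNG state is saved and
restored, so library calls never perturb a session. Identical configs and
seeds produce byte-identical outputs. Geometric identities (frame
invariants, pose/measurement round trips, yaw invariance) are asserted at
1e-9–1e-6; statistical recoveries at their closed-form or generator-known
values; metric implementations against independently coded brute-force
oracles at 1e-10.

# Known limitations

* The files-mode adapter expects the package's wide CSV/TSV dialect; public
  deposits with other layouts need a one-off converter.
* Transverse-plane exercises and left-side evaluation are out of scope (the
  marker set covers the right side only).
* The alignment assumes a rigid time offset; clock drift or non-rigid time
  warps are not modeled.
* With strongly negative amplitude intercepts the ground-truth clamp at 0°
  activates near rest and the injected linear relation is only exact over
  the unclamped range.
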