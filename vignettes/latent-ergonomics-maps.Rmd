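---
title: "Latent Ergonomics Maps: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent Ergonomics Maps: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the bundled synthetic data can and cannot
tell you about real recordings.

## The digital human model

The body is a rigid multi-body tree of 23 segments: pelvis (the floating
root), four spine levels (L5, L3, T12, T8), neck and head, and symmetric
clavicle–upper-arm–forearm–hand and thigh–shank–foot–toe chains. Every
non-root segment carries a triplet of one-DoF revolute joints, giving
66 actuated coordinates; the pelvis adds an unactuated 6-DoF base, so the
extended configuration is `q̄ = (x_F, q) ∈ R^72`.

**Axes.** The world frame is x forward, y to the subject's left, z up;
segments rest aligned with the world (standing, arms hanging). The triplet
order is flexion → abduction → axial rotation as an intrinsic Y–X–Z
sequence: flexion rotates about the lateral (y) axis, abduction about the
forward (x) axis, axial rotation about the segment's long (z) axis. With
z up and segments resting along ±z, these are the only axes for which the
three names mean what an ergonomist expects; in particular a "flexion"
about the vertical axis would be a no-op for a vertical segment. Abduction
is positive toward +y for *every* joint, so outward abduction of right
limbs is negative; the payoff is that left–right mirroring is exactly
"swap the side triplets and negate abduction/rotation", which the
augmentation and its tests rely on.

**Anthropometry.** Segment lengths and joint offsets are fixed fractions
of stature, masses fixed fractions of body mass, in the style of the
classical adult anthropometry tables; the trunk mass is split across the
pelvis and spine levels, and the coefficients are renormalized at build
time so segment masses sum to the subject mass exactly. The stacked
leg–trunk–head fractions sum to 1.0 of stature, so the standing model
spans the input height (tested within 5%). Each segment is a homogeneous
geometric primitive — parallelepiped trunk levels, cylinder limbs, sphere
head — whose dimensions are stature fractions; inertia tensors follow
from the primitive formulas. These coefficients are a literature-style
composite, not a fit to any one subject; they are the right order of
magnitude for adult bodies and exactly reproducible.

**Kinematics.** Forward kinematics composes rest offsets and joint
rotations down the tree; the link Jacobian stacks, for each joint on the
root-to-link path, the world joint axis (angular rows) and its cross
product with the lever to the point of interest (linear rows), plus an
identity/skew block for the floating base. Correctness is established
against central finite differences of the kinematics (≤ 1e-6 absolute on
100 random postures).

## Inverse dynamics

Joint torques solve the floating-base Lagrangian equation
`M q̈ + C q̇ + G = Sᵀτ + Σ Jᵀf` for the actuated coordinates. Rather than
assembling `M`, `C`, `G`, the package runs a recursive Newton–Euler sweep
in world coordinates (O(n), no symbolic matrices); the equivalence is
tested against an analytically derived planar double/triple pendulum
oracle to 1e-6 N·m, and the static limit against a potential-energy
finite-difference oracle. External wrenches are applied at segment frame
origins in the world frame, so linearity `τ({f}) − τ(∅) = −Σ Jᵀf` holds
exactly and is tested.

Ground reaction is approximated by the body weight applied upward at the
foot frames: equal halves when both feet are within 2 cm of the lowest
foot, otherwise all on the lower foot (the threshold and split are
configurable; the equal split is the sensible default for the standing
activities generated here). This deliberately ignores inertial and
center-of-pressure effects — the approximation that makes the estimator
usable when only skeleton data is available. Velocities and accelerations
default to zero (`quasi_static = TRUE` forces that), which is the right
regime for posture-level feedback; full states can be supplied.

Arm manipulability is the product of the singular values of the
positional chain Jacobian taken at the segment tip (twice the COM offset
of the homogeneous primitive); on a planar two-link chain this reduces to
the textbook `l₁ l₂ |sin q₂|`, which the tests verify, and it is invariant
to the base pose.

## RULA and its continuous relaxation

The discrete scorer implements the published worksheet: banded joint
angles → sub-scores → Table A (arm) and Table B (neck/trunk/legs) →
muscle-use and force/load additions → Table C grand score in 1–7. Both
arms are scored and the worse side is kept. Checkbox adjustments
(shoulder raised, arm abducted, arm across the midline, wrist deviated,
neck/trunk twist and side-bend) are derived from angles with fixed
thresholds (10°, 30°, 10°, 10°, 20°) documented in `rula_tables()`; the
worksheet leaves these to the observer, so the thresholds are package
choices, stated as such. Band edges at 0° would put the neutral posture
on a boundary, so the neutral bands carry a ±5° tolerance (wrist, trunk,
and the neck's extension edge). The tables are verified against an
independently hand-entered copy on band-corner postures, and exhaustive
enumeration confirms the grand score spans exactly 1–7.

RULA-C replaces both discretizations:

* **Within joints**, each band contributes a second-degree polynomial
  segment with its vertex at the band midpoint (value = the band score)
  meeting the neighbouring band at the edge, where the value is the mean
  of the two adjacent scores; beyond the outermost midpoints the extreme
  score is held. The interpolant is continuous everywhere and exact at
  band midpoints. A single global quadratic per joint was tried first and
  rejected: the neck pattern (extension → 4 adjacent to neutral → 1) is
  not representable, and the fit degraded both the neutral value and the
  ordering agreement with discrete RULA.
* **Checkbox adjustments** enter as linear ramps 0 → 1 over 10° centered
  on the discrete thresholds, preserving continuity while tracking the
  discrete scorer.
* **Across joints**, Tables A, B and C are replaced by least-squares
  linear models (intercept + one weight per sub-score) fitted over every
  table cell, *anchored at the neutral cell*: an equality constraint
  forces the fitted value 1 when all regressors are 1. Unconstrained
  planes overshoot the best corner of these saturating tables (the B
  plane reads 2.0 at the all-ones cell) and lift the floor of the
  continuous score; anchoring restores the neutral reference at a
  negligible cost in overall fit (Table C is reproduced within one score
  unit after the [1, 7] clamp).

The result is continuous (max jump ≤ 0.01 over 0.01° sweeps, tested),
within 1 score unit of discrete RULA on average over uniform random
postures, and Spearman ≥ 0.9 against discrete RULA on generated motion
streams. On uniform draws from the whole joint-limit box the ordering
agreement is lower (~0.65): a linear composition cannot reproduce the
tables' interactions far from the regions real motions visit, which is a
known and accepted limit of the relaxation.

Local scores color body locations: shoulders ← upper-arm sub-score,
elbows ← lower-arm, back ← trunk, torso ← mean of trunk and neck,
knees ← a continuous knee-flexion ramp (the worksheet has no per-knee
band), ankles ← legs. Task normalization maps each location to [0, 1]
using the maximum registered during calibration, clamping above-max
values; the triadic colormap is exact at its endpoints (green 0, yellow
0.5, red 1).

## The relational VAE

Architecture 66–200–2–200–66: rectifier hidden layers, identity output,
and a tanh-bounded latent. The encoder produces a Gaussian in a pre-squash
space; the code used everywhere (maps, traces) is `z = tanh(z₀)`, so the
latent lives in [−1, 1]² and the default map bounds cover it exactly. The
decoder likelihood is Gaussian with fixed observation noise σ_x = 0.1 in
normalized units — the scale of the generator's angle noise after
normalization — which balances the reconstruction and KL terms for data
confined to the unit cube (σ_x = 1 would let the KL collapse the 2-D
latent). The loss is

`L = (1 − α)(reconstruction NLL + β·KL) + α · relation NLL`

with the relation NLL the Gaussian error of a small head predicting the
unit-scaled RULA-C score from `z`. At α = 0 this is exactly the standard
evidence lower bound; α defaults to 0.2. The head is a one-hidden-layer
tanh network (2→8→1): the score surface over a 2-D latent is bowl-shaped,
and an affine head demonstrably cannot track it (held-out r ≈ 0.5 affine
vs ≈ 0.99 with the hidden layer). β ramps linearly from 0 to 1 over the
first 20 epochs — standard warm-up against early posterior collapse.

Training is minibatch Adam (batch 128, rate 1e-3, 300 epochs by default)
with hand-derived gradients, verified against finite differences to 1e-6.
All randomness flows from the configured seed; identical runs are
bit-identical, which the determinism tests and the seeded demo rely on.
Pre-training on the broad synthetic mixture and fine-tuning on a
task-specific set (`vae_fine_tune`, a tenth of the learning rate, no KL
warm-up) mirrors the intended workflow; the tests check the task-set
reconstruction does not degrade.

## Maps and traces

A Latent Ergonomics Map samples the latent square on a uniform grid
(default 100 × 100 = 10,000 cells, bounds [−1, 1]² matching the tanh
latent), decodes each cell, inverts the normalization, and scores the
reconstructed posture; one map per score kind (discrete RULA, RULA-C,
quasi-static mean absolute torque, arm manipulability). Rendering uses
the triadic code — discrete bands for RULA (1–2 green, 3–4 yellow, 5–7
red, the RULA action levels), continuous colors otherwise (manipulability
inverted so red marks poor capability) — with the numeric map always
exported alongside the image. Traces use the posterior mean (not a
sample) for online stability, read the nearest cell, and clamp
out-of-bounds points to the border.

Two quantitative properties define a usable map, and both are tested at
the study scale (5,000 training postures): held-out reconstruction RMSE
≤ 0.05 in normalized units, and Pearson r ≥ 0.8 between the true score of
a held-out posture and the map value at its encoded point (measured
≈ 0.98). The encoder–decoder round trip of a grid cell is *not*
cell-exact: a KL-regularized pair is contractive toward the data
manifold, and the measured median round-trip displacement near the
manifold is ≈ 0.06 of latent units (three cell widths). The map-fidelity
correlation, not cell-exactness, is the property that matters for
reading scores off the map.

## The synthetic motion generator

The generator emulates the study conditions: keyframed archetypes
(neutral, stoop with 70° total trunk flexion, squat with 90° knees,
overhead with 150° shoulder flexion, carry with 90° elbows, a stride
pair) cycled per activity and interpolated with cubic ease-in/ease-out
segments (zero velocity at keyframes), plus zero-mean joint noise
truncated at ±3σ and clamped to the joint limits. Keyframe angles sit
squarely inside named RULA bands so the discrete scores of the archetypes
are unambiguous. The noise default is σ = 0.02 rad (≈ 1.1°), the
joint-angle accuracy class of the inertial motion-capture suits the
generator stands in for; i.i.d. frame noise is irreducible by any
reconstruction, so this choice directly sets the floor (≈ 0.04
normalized) under the achievable held-out RMSE. Training sets mix all
seven activities in equal shares, augment with mirrored copies and
temporal midpoints, normalize by fixed joint limits (invertible,
task-independent), and pair each posture with RULA-C/7.

What the generator does **not** reproduce: temporally correlated residual
motion (real mocap error drifts; ours is white), ground-contact physics
and balance shifts, load-dependent posture changes, inter-subject
variability, and real task context. Passing tests therefore demonstrate
that the pipeline recovers structure it is known to contain — parameter
recovery, not field validity. On real recordings the latent geometry,
the irreducible error, and the calibrated task maxima will differ; the
interfaces (motion CSV, calibration, fine-tuning) are where real data
plugs in.

The impedance wrench source implements the task-space law
`w = D(ẋ_d − ẋ) + K(x_d − x)` with diagonal stiffness (compliant 500 N/m
and stiff 1000 N/m are the two study settings) and factorized damping
`D = 2ζ√K`, ζ = 0.7 by default (the damping ratio is not dictated by the
task; 0.7 keeps a unit-mass step response within 5% overshoot, tested by
simulation).

## Numerical choices and degenerate inputs

Rotations use Rodrigues' formula; base orientation is extrinsic XYZ Euler
in files and a rotation matrix internally. Calibration rejects single-
posture datasets and widens dimensions that do not move (±0.01 rad, with
a warning) so the normalization stays invertible. Decoded postures clamp
to [0, 1] before de-normalization; scores above a task maximum clamp to 1.
The foot-wrench split breaks ties toward equal sharing (2 cm tolerance).
Motion parsing validates the header layout and reports the first
offending line. Problem sizes used throughout — 5,000 training postures,
300 epochs, 100 × 100 maps, 1,000-posture score comparisons — are the
package's reference scale: large enough for stable estimates, small
enough to rerun routinely.

## Known limitations

The anthropometric table is a fixed adult composite; no per-segment
personalization beyond global height/mass scaling. The foot-wrench
approximation biases lower-body torques during dynamic or single-support
phases. RULA-C inherits RULA's blind spots (no duty cycle or repetition
over long horizons) and adds its own far from the data manifold. The 2-D
latent loses information by construction; scores read off the map are
estimates whose fidelity should be re-measured (as the acceptance script
does) whenever the training distribution changes. Checkpoints are RDS
containers, portable across R sessions but not across languages.
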