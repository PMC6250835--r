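---
title: "Methods: the sit-to-stand muscle-dynamics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sit-to-stand muscle-dynamics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standup)
```

This vignette is the package's own account of the models and numerical
choices behind its sit-to-stand (StS) analysis of a canine hindlimb. It
is written for a reader who wants to know *why* the pipeline is built the
way it is, what its assumptions buy and cost, and what passing the test
suite does and does not demonstrate.

## The musculoskeletal model

The limb is a chain of four rigid segments — pelvis, thigh, shank, foot —
articulated by hip, knee and ankle joints. Each joint carries up to three
rotational degrees of freedom applied in the Cardan order
flexion/extension (about Y), ad/abduction (about X′), internal/external
rotation (about Z″); the pelvis root has six free coordinates. Axes are
oriented so that **extension, abduction and external rotation are always
positive**, both for angles and for moments, and all joint angles are
zero in a straight-limb reference pose (X cranial, Y to the animal's
left, Z up). Knee and ankle non-sagittal DOFs are locked at zero in
nominal processing — those joints permit little such motion anatomically
and marker-based estimates of them are unreliable — and can be unlocked
as a sensitivity variant.

Muscle paths are **posture-independent via-point polylines** (2–5 points
per muscle). Wrapping surfaces were deliberately not implemented: what
the redundancy analysis consumes is the tendon-excursion moment arm
`r = −∂L/∂q`, and a small number of well-placed via points (notably a
patellar pulley pair for the knee extensors and a calcaneal-tuber point
for the Achilles group) reproduces arms of anatomically sensible sign and
magnitude (hip extensors ≈2–4 cm, knee extensors ≈1.5–2.5 cm, ankle
extensors ≈2–3.5 cm) across the full crouch-to-stand range. One emergent
behaviour is worth noting: in the deeply flexed crouch the long digital
extensor's ankle arm flips to the extensor (plantarflexor) side before
reverting as the limb extends — the same reversal reported for this
muscle in deeply crouched postures, arising purely from the geometry of a
cranial tendon path around a maximally flexed tarsus.

Muscle architecture comes from the packaged dissection table: PCSA (cm²),
pennation at optimal fibre length (deg), optimal fibre length and tendon
slack length (cm). Maximal isometric force is PCSA × 300 kN m⁻², rounded
to the newton as tabulated; the printed Fmax values carry **no pennation
factor**, so the table's values are used verbatim rather than recomputed
(recomputation with cos α would contradict several printed entries).

### Rigid-tendon Hill muscle

Fibre state follows the constant-height rigid-tendon construction:
muscle height `h = l_opt·sin α₀` is fixed, the projected fibre length is
`p = L_MTU − TSL`, fibre length is `√(h² + p²)`, and
`cos α = p / l_fibre`. Active capacity is

`F = a · Fmax · f_L(l̃) · cos α`,  `f_L(l̃) = max(0, 1 − ((l̃ − 1)/0.5)²)`.

The force–length curve is the simplest symmetric curve honouring the
conventional 0.5–1.5 operating bounds with maximum 1 at optimum; no
passive element and no force–velocity scaling enter the optimization
(static optimization resolves each frame independently, so fibre
velocities are never formed). A muscle whose MTU momentarily falls below
its tendon slack length is treated as slack — zero capacity — rather
than as an error, which matters only in the −/+10% TSL sensitivity
variants.

### Tendon-slack-length calibration

The tabulated TSLs belong to the dissected specimen's geometry, not to
the package's via-point paths, so the default model calibrates its own in
two stages that mirror how such tables are assembled:

1. TSL is set so the fibre is at optimal length in the standing posture,
   then nudged by bisection (tolerance 10⁻⁶ cm) into the 0.8–1.2
   standing window if needed.
2. Where a 21-posture crouch-to-stand sweep still leaves the 0.5–1.5
   band, optimal fibre length is grown by the minimal amount — with TSL
   shortened equally, conserving MTU rest length to <10⁻⁹ cm — that
   restores it.

Stage 2 fires for the short-fibred, long-tendoned distal muscles
(gastrocnemii, deep digital flexor, lateral digital extensor), exactly
the group whose fibre lengths had to be grown severalfold in the source
architecture table; the calibration log is attached to the model as
`attr(model, "tsl_calibration")`.

## Kinematics

Cluster poses are per-frame least-squares rigid transforms (Kabsch/SVD
with det +1) from a static calibration template to the observed markers;
clusters whose centred template has a singular-value ratio below 10⁻⁶
(collinear) are rejected. Joint angles are Cardan Y–X′–Z″ decompositions
of the parent-relative rotation, sign-mapped to extension-positive and
unwrapped. Near gimbal lock (|cos θₓ| < 10⁻⁶) the third angle is set to
zero with a loud warning — deterministic and visible beats silently
ill-conditioned.

Gap handling implements the stationary-crouch rationale: leading gaps are
back-filled with the first valid sample (hidden medial foot markers in
the crouch belong to a limb that has not yet moved), interior gaps up to
0.1 s are linearly interpolated, longer ones are flagged and left
missing.

StS events are not part of the source conventions, so the package defines
them explicitly and config-exposed: onset when any joint's extension
velocity exceeds 5 °/s sustained for 50 ms; end when all angles have
settled within 2° of their final standing values. The ~45° outlier
screen is operationalized as the **maximum** absolute deviation from the
group mean over the cycle (a mean-deviation mode is available), applied
per channel. Ensemble averages are subject-first, so unbalanced trial
counts cannot bias the grand mean.

## Filtering and differentiation

All filters are zero-phase (forward–backward) Butterworth — markers and
force plates 4th order / 6 Hz, inverse-dynamics coordinate prefilter 3rd
order / 6 Hz — because %StS event timing must not be phase-shifted; the
effective attenuation is the squared single-pass response. The
forward–backward pass is wrapped in **odd-reflection edge padding** of
10 cutoff-periods: the plain zero-initial-condition implementation
distorts edges badly (a constant input came back 75% wrong near the
ends), while odd reflection passes constants and linear trends through
exactly. Derivatives are central differences (one-sided at the ends);
moment arms use a central difference with step 10⁻⁴ rad, which agrees
with analytic pulley arms to <10⁻⁶ m.

## Inverse dynamics

A recursive Newton–Euler pass runs foot→shank→thigh→pelvis with the
ground-reaction force applied at the centre of pressure. Segment angular
velocities come from `Ṙ Rᵀ` (central differences on the rotation
matrices), inertia tensors are rotated to world axes per frame, and the
unbalanced force and torque at the pelvis are reported as **residuals** —
the stand-in for the other three limbs and trunk, allowed to vary
freely. A quasi-static switch zeroes all rates; on a 4 s synthetic
transition the full and quasi-static solutions agree within 5% RMS at
every sagittal DOF. At the default 1.14 s duration they deliberately do
*not* at the hip: compressing 53.4° of hip extension into the first 20%
of the cycle (~0.23 s) produces ~40 rad s⁻² of genuine angular
acceleration, so the full dynamic solution is the honest one and the
quasi-static label applies to the movement only loosely. Frames applying
more than 5 N of ground force without a defined CoP abort the analysis;
smaller forces are dropped as noise.

## Static optimization

Reserve actuators with "optimal torque" R₀ enter the objective as
`(reserve/R₀)²` beside `Σ a²`; eliminating them through the (hard)
moment-equilibrium constraint leaves a strictly convex box-constrained
QP per frame, solved **exactly** by a primal active-set method (clamp the
worst bound violation, release the worst multiplier violation; finite
termination under strict convexity, tolerance 10⁻¹⁰). Because reserves
are computed as `τ − Σ rF` after the solve, moment balance holds to
machine precision at every frame — the validation suite measures ~10⁻¹⁵
relative residual. Muscles whose capacity `Fmax·f_L·cos α` falls below
10⁻⁹ of Fmax are excluded from the frame's constraint matrix to keep it
well scaled.

R₀ defaults to 1 Nm, the conventional setting that makes reserves
expensive relative to muscles in real analyses. Exactness tests
(activation recovery on square systems, the two-muscle Lagrange share
`aᵢ = τkᵢ/Σk²`) configure R₀ = 10⁻⁴ Nm so the reserve penalty dominates
and the solution approaches the hard-constrained optimum to ≤10⁻⁶; with
R₀ = 1 the same solutions are soft by design, off by O(R₀²/k²).

Reporting follows the 20%/20% convention — a muscle appears in outputs
when peak activation exceeds 0.2 or peak force exceeds 0.2 body weight —
and reserve acceptability uses the 1 Nm / 5%-of-inverse-dynamics
thresholds, with percentages computed from unrounded series.

## The synthetic trial generator

The generator emulates the *statistical shape* of measured greyhound StS
trials, providing ground truth for every stage:

* proximal-to-distal extension: logistic transitions confined to timing
  windows (hip 0–20%, knee 10–50%, ankle 25–60% of StS), normalized to
  hit the crouched and standing angles exactly; default excursions 53.4°,
  78.5°, 88.7°;
* trial duration 1.14 s (SD 0.16 s between trials), sampled at 180 Hz;
* combined hindlimb vertical GRF rising from a 0.45 BW crouched share to
  a 0.55 BW standing share with a peak of 1.0 BW at 20% StS, a 0.1 BW
  craniad pulse at 15% StS, and zero-mean mediolateral noise; plate
  records are synthesized at 1,800 Hz only where the decimation path
  itself is under test;
* a centre of pressure travelling craniad from heel to toe as the foot
  goes plantigrade→digitigrade. The travel is bounded by the planted
  foot (trials require the paws not to move), so the configured 0.4 m
  excursion acts as a cap; an unbounded lab-frame excursion would place
  the CoP behind the support polygon and manufacture nonphysical knee
  and ankle torque demands;
* markers by forward kinematics with i.i.d. Gaussian noise (default SD
  1 mm, typical of optical capture) and optional leading gaps on named
  medial foot markers; the pelvis trajectory pins the toe to a fixed
  ground point, which yields a consistent rising motion without a
  contact model;
* all randomness flows from one integer seed; identical seeds give
  bit-identical trials and different seeds share identical ground truth.

What passing on synthetic data does **not** show: the generator has no
soft-tissue artifact (markers ride rigidly on segments), no bilateral
asymmetry or rolling strategies, no trunk or forelimb mechanics beyond
the weight-share endpoints, and its GRF is consistent with the kinematics
only up to the pelvis residuals. Agreement of recovered quantities with
ground truth validates the *pipeline*, not the biological fidelity of any
single trial.

## Sensitivity analyses

Three variants re-run the solved trial: TSL ± 10% (applied uniformly;
per-muscle perturbation is available for diagnostics), unlocking the
measured non-sagittal knee/ankle rotations (which adds four equality
constraints per frame and therefore can never lower the optimum), and an
alternative trial (a different seed). With a rigid tendon, −10% TSL
shifts a muscle's normalized fibre length up by `0.1·TSL/l_opt` at fixed
MTU length — for distal muscles with TSL/l_opt > 5 that is a shift of
+0.5 or more, a substantial fraction of the whole operating band, which
is why the distal limb dominates the sensitivity results. Percent changes
between runs guard near-zero baselines (<10⁻³ activation) by reporting
absolute differences instead.

## Known limitations

* Via-point geometry is synthetic: functional (signs, magnitudes,
  crossings) rather than specimen-accurate; absolute muscle forces
  inherit that approximation.
* Rigid tendons overstate fibre excursions for long-tendoned muscles;
  the TSL sensitivity brackets, but does not remove, that bias.
* The anatomical-frame construction from landmarks is one reasonable
  convention (long axis proximal→distal, flexion axis from the
  epicondyle pair, orthogonalized); published marker sets do not pin it
  down uniquely.
* Problem sizes in the tests (trials of 20–205 frames, 1,000-replicate
  Monte-Carlo for cluster noise) were chosen as the smallest that
  exercise every code path with stable statistics.
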