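---
title: "Methods: simulating mouse hindlimb trotting with mousegait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating mouse hindlimb trotting with mousegait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousegait)
```

# The model and its assumptions

`mousegait` simulates a single trotting stride of one mouse hindlimb as a
sagittal-plane rigid-body chain of four bodies — pelvis+torso (rigidly
joined), thigh, lower leg (shank) and foot — actuated by Hill-type
musculotendon units (MTUs). The generalized coordinates (gencoords) are
pelvic tilt, hip flexion, hip adduction, knee extension and ankle
flexion, all zero at the fully extended reference pose in which the limb
lies straight and caudal, in line with a horizontal pelvis. Positive
senses are: pelvic tilt = cranial end up, hip flexion = thigh swings
cranially, knee extension = knee straightens (gait values are therefore
negative), ankle flexion = plantarflexion, hip adduction = limb toward
the midline. The published description of this system is internally
inconsistent about the ankle sign (its figure convention calls positive
plantarflexion while its moment text labels a negative moment
"plantarflexion"); this package adopts the figure convention —
**positive gencoord and positive moment = plantarflexion** — everywhere.

Segment masses, centers of mass and inertia tensors are the published
values (`segment_inertia_table()`), kept exactly as printed; the printed
foot frame has its long axis on x and is rotated onto the chain
convention (origin at the proximal joint, −y distal). Segment *lengths*
are not published; the defaults (thigh and shank 14.4 mm, pelvis 10 mm,
foot 9 mm, torso 58.8 mm) are model choices consistent with the printed
mid-segment centers of mass and are what the procedural muscle geometry
is built on.

## MTU parameters and procedural geometry

Each MTU carries the published force-generating constants
(`mtu_parameter_table()`): maximum isometric force `f_max` (N), optimal
fiber length `l_opt` (m), tendon slack length `l_ts` (m), pennation
angle at optimal fiber length (degrees). The printed table contains 42
rows; the source text elsewhere counts 44 MTUs in the deposited model
(and names a muscle, FHL, that the printed table lacks), so two rows
were evidently lost from the printed version. This package carries
exactly the 42 printed rows rather than inventing values for the
missing two.

Muscle *paths* are not published (they live in the deposited 3-D model),
so they are generated procedurally: every MTU receives a three-point
pulley path about the joint its functional group crosses — an origin on
the proximal segment, a pulley point fixed to the proximal segment at a
perpendicular offset from the joint center, and an insertion on the
distal segment. The construction enforces two contracts:

* the path length at the reference pose equals
  `l_ts + l_opt*cos(pennation0)` **exactly**, so the normalized fiber
  length is 1 at full extension under the rigid-tendon model; and
* the sign of the moment arm about the group's primary coordinate
  matches the group (hip flexors positive about hip flexion, extensors
  negative, plantarflexors positive about ankle flexion, dorsiflexors
  negative, adductors positive about hip adduction), verified
  numerically. Sign calibration is performed at a mid-gait pose (hip
  flexed 45°, knee −45°) because the fully extended reference pose is
  degenerate for hip adduction — the thigh lies along the adduction
  axis and every adduction moment arm vanishes there.

Perpendicular offsets (= moment-arm magnitudes near the calibration
pose) are 2 mm at the hip, 1.5 mm at knee/ankle and for adductors, and
0.5 mm for groups whose primary action is an unmodeled degree of
freedom (hip long-axis rotators, ankle everters). The pulley layout
keeps the moment-arm sign stable across the gait range of joint
rotations, unlike a plain two-point chord, which sweeps through the
joint center under large rotations.

**Limitation — mono-articular paths.** Every synthetic path spans one
joint (hip muscles also weakly couple to hip adduction). The real
hamstrings, rectus femoris and gastrocnemii are bi-articular; their knee
actions are therefore missing here, and the knee-extension reserve
actuator picks up knee-flexion demands that hamstrings would carry in
the deposited model. This is visible in the diagnostics as substantial
knee reserve shares and is the main respect in which the synthetic
geometry is weaker than the deposited one.

## Muscle mechanics

The Hill-type curves are smooth closed forms with documented, tunable
constants (`default_muscle_curves()`): Gaussian active force-length of
width 0.45; exponential passive force-length reaching `f_max` at strain
0.6; a Hill hyperbola force-velocity branch (curvature 0.25, zero force
at maximal shortening `v_max*l_opt`) joined C¹-continuously to an
eccentric plateau of 1.4; and an exponential-toe tendon reaching
`f_max` at 4.9% strain, continued linearly beyond the toe so the curve
stays finite and monotone. `v_max` is not published; the default is 10
optimal fiber lengths per second, configurable per model.

Two force modes exist. *Rigid-tendon* mode (the static-optimization
simplification) puts all length change in the fiber
(`fiber = sqrt((l_mtu − l_ts)² + w²)` with constant thickness
`w = l_opt sin α₀`) and **omits passive fiber force**. *Compliant* mode
solves the fiber–tendon force balance by bracketing root search
(tolerance 1e-9 relative), includes passive fiber force, and evaluates
the force-velocity multiplier at the rigid-tendon fiber velocity — a
quasi-static approximation chosen so the compliant force needs no fiber
state variable; in the stiff-tendon limit it converges to rigid mode
(verified within 1% at 100× stiffness). A slack tendon
(`l_mtu ≤ l_ts`) contributes zero force downstream.

Excitation→activation dynamics are first order with exact exponential
updates, τ_act = 10 ms and τ_deact = 40 ms, clamped to [0, 1].

# Gait processing

Markers (iliac crest, hip, knee, ankle, MTP) are low-pass filtered with
a zero-phase Butterworth filter, cutoff 20 Hz. The order (4 per pass)
and zero-phase application are not stated in the source and follow
standard gait practice; both are arguments. Because no digital-filter
package ships in the supported runtime, the design (analog prototype →
pre-warp → bilinear transform) and forward–backward application with
steady-state initial conditions are implemented in the package and
tested against closed-form magnitude responses.

Angles are inter-marker angles converted to gencoords; strides are
resampled to a common normalized-time base by cubic splines (`"fmm"`
ends, which reproduce cubic polynomials exactly) and pooled as
pointwise means with **normal-theory 95% confidence intervals,
1.96·SE** — the source does not state its CI construction; bootstrap
was the alternative and normal theory was chosen for determinism and
because pooled gait channels at n = 44 are well into the CLT regime.
GRFs are filtered the same way, normalized to whole-stride time, and
are identically zero during swing by construction. A stride runs swing
first; the duty factor is `1 − transition fraction`.

# Inverse and forward dynamics

Inverse dynamics uses the virtual-work (Jacobian) form
τⱼ = Σᵢ mᵢ(aᵢ − g)·J<sub>i</sub>[,j] + Iᵢφ̈ᵢS[i,j] −
J<sub>CoP</sub>[,j]·F, with CoM accelerations obtained by repeated
central differences of the forward-kinematic positions on the filtered
coordinate series (one-sided second-order stencils at the ends). A
spline-derivative alternative was considered and rejected: on filtered
series the two agree, and central differences are the stated
convention. Fewer than 50 samples per stride triggers a warning.
Hip adduction is a decoupled frontal-plane single-DoF balance (composite
limb pendulum about the hip's cranial axis, vertical GRF supporting the
abducted limb at the CoP lever): full 3-D dynamics are unidentifiable
from 2-D sagittal recordings, and the published treatment likewise
handles this coordinate with its own reserve actuator.

The CoP is fixed in the foot frame at the mid-point of the distal end of
the metatarsals (5 mm along the 9-mm foot, i.e. phalanges ≈ 4 mm, which
makes the ±2 mm sensitivity offsets 50% of phalanx length as in the
source); `cop_sensitivity()` re-runs inverse dynamics per offset and
reports peak-magnitude stance-moment deltas. During forward dynamics the
CoP stays fixed *in the foot frame* (the source is silent on this; the
alternative, ground-frame fixing, would detach the force from the foot
as the simulation deviates from the measured kinematics).

Forward dynamics integrates with an in-package adaptive Dormand–Prince
RK45 (no ODE package is assumed; relative tolerance 1e-6 by default,
dense output by cubic Hermite interpolation). The torque-driven mode is
the module's central correctness property: driving the chain with the
moments from inverse dynamics reproduces the input kinematics to well
under 1° RMS per coordinate. The muscle-driven mode uses rigid-tendon
muscle forces (activation states only, no fiber states) — a deliberate
simplification: tendon compliance enters the work pipeline through the
muscle-analysis path, and compliant-fiber state dynamics would add 42
stiff states for little benefit at this model scale. Coordinate limit
forces (defaults: stiffness 0.5 N·m/rad, damping 0.01 N·m·s/rad,
2° quadratic smoothing at the coordinate range limits; the source's
supplementary values are not in its text) keep the unconstrained
simulation inside the coordinate ranges; they also make the system
stiff when engaged, which is why the muscle-driven stride simulation is
opt-in in the pipeline (`run_forward_dynamics = TRUE`).

# Static optimization

At each timestep, independently (no energy transfer between steps), the
package minimizes Σaᵢ² + Σⱼwⱼ(reserveⱼ/R0ⱼ)² + w_F·|F_res/F0|² subject
to the moment balance and 0 ≤ aᵢ ≤ 1, with rigid-tendon, passive-free
maximal forces F̄ᵢ(q, q̇). Reserves are eliminated exactly as the
constraint remainder, so the **moment balance holds to machine
precision at every accepted timestep** and the problem becomes a
strictly convex box-bounded quadratic program in (activations,
residuals), solved by an in-package working-set active-set method whose
optimality is certified by the reported KKT residual (and, in the test
suite, by grid-search and L-BFGS-B oracles).

Cost structure (the source states only "high cost" for reserves and "no
cost" for residuals/pelvic tilt; exact magnitudes are unpublished and
all are arguments):

* limb-coordinate reserves: weight 1 with optimal moment R0 = 1 N·mm,
  so unit reserve output costs as much as a fully activated muscle;
* the pelvic-tilt reserve: weight 1e-3 with R0 = 50 N·mm (the scale of
  the pelvic-tilt moment). No muscle spans pelvic tilt, so this cheap
  reserve carries that coordinate's entire moment, reproducing the
  published actuator structure;
* residual forces F_X, F_Y at the model CoM: weight 1e-3 with
  normalization 0.01 N, acting only through the pelvis–ground
  coordinate set (the base translations are locked), so they absorb
  trunk/forelimb inconsistencies without substituting for interior
  joint muscles. "No cost" is implemented as *negligible* cost to keep
  the program strictly convex.

At the default weights the quadratic trade-off provably shares a small
percentage of each moment into the reserve; analyses that require exact
activation recovery (e.g. the parameter-recovery oracle in the test
suite) raise `reserve_weight`, which is part of the documented
interface, not a test-only backdoor. Activations below 0.01 are
reported "not active". Diagnostics report signed reserve-to-net-moment
shares and residual-to-peak-GRF ratios against the 5% reliability
threshold.

# Work analysis and classification

Actuator power is P = F·(−dL/dt) (shortening under tension positive;
reserve power is moment × coordinate velocity). Work integrals are
trapezoidal with the swing/stance boundary node interpolated so that
phase terms tile the stride exactly: net = positive + negative holds to
rounding, and swing + stance = whole-stride by linear-exactness of the
trapezoid rule. Outputs are mJ.

The muscle-analysis path re-evaluates each MTU along the measured
kinematics with its activation constrained to the static-optimization
solution and tendon compliance accounted for; the forward-dynamics path
uses simulated states; both feed the same work module. Phase integrals
use the stride time base (the source is ambiguous between stance- and
stride-normalized bases; stride was chosen so swing and stance windows
are complementary).

Classification thresholds are not quantified in the source. Defaults:
inactive if peak force < 1% of `f_max`; then motor/brake if |net| work
exceeds 10% of the actuator's largest phase-work magnitude (positive /
negative respectively); spring if net is within that band while both
total positive and |negative| exceed it; strut otherwise. Because the
10% band is self-normalized, an actuator with physically negligible
work could never reach "strut" through it, so an absolute floor
(`work_floor`, default 1e-4 mJ — orders of magnitude below real muscle
work at this scale) short-circuits to strut. The report always carries
the raw numbers next to the label.

# The synthetic gait world

The generator's defaults are the published landmark values: stride
duration 0.128 s with the swing→stance transition at 0.072 s (duty
factor 0.4375, printed as 0.44), speed 0.59 m/s, subject mass 18.7 g,
vertical GRF peaking at 120% body weight at 55.1% of stance, braking
and propulsive fore-aft peaks of 10.9% and 8.19% body weight, marker
rate 250 Hz, g = 9.8 m/s² in body-weight normalization (the value that
reproduces the printed percentages). Note the published "0.21 N (120%
of body mass)" pair is itself inconsistent at 18.7 g (120% BW =
0.22 N); the generator follows the body-weight fraction.

Joint angles are two-harmonic truncated Fourier series per coordinate —
periodic, hence continuous in value and velocity across the stride. The
per-coordinate means and amplitudes (hip 35 ± ~24°, knee −50 ± ~20°,
ankle 0 ± ~26°, pelvic tilt 15 ± 4°, adduction 5 ± 4°) are model
choices of gait-plausible ranges; the knee wave can be rescaled to hit
a stated stance excursion exactly (`knee_stance_excursion_deg = 18`
reproduces the published stance knee excursion). The vertical GRF is a
beta-shaped bump whose mode is placed analytically at the stated stance
fraction; the fore-aft channel is two half-sines with the stated lobe
peaks. Markers are forward kinematics of the angles plus i.i.d.
Gaussian digitization noise; all randomness flows through the seed, and
identical (parameters, seed) give byte-identical trials.

**What a green test does and does not establish.** The synthetic world
exercises every pipeline contract — filtering, angle recovery, pooling,
moment balance, activation bounds, work bookkeeping, determinism — but
it is not a replication of the laboratory trials: the via-point
geometry is synthetic and mono-articular, the joint waves are idealized,
and inter-trial variability is a simple amplitude/duration scaling.
Published headline numbers that depend on the deposited 3-D model and
raw recordings (peak joint moments, per-muscle work values, CoP
sensitivity deltas) are therefore *not* asserted against synthetic
output; the package's importers (`read_osim()`, the delimited trial
readers) exist so those analyses can be re-run when the deposited data
are available.

# Numerical choices

* Angles radians internally, degrees at user interfaces; moments N·m
  internally, N·mm (×1000 exactly) in reports.
* Moment arms by central difference of MTU length (step 1e-5 rad),
  tested against Richardson-extrapolated derivatives to < 1e-7 m.
* JSON model/config serialization writes 17 significant digits so
  read/write round-trips are bit-exact.
* The box-QP working-set solver takes exact subspace steps with
  blocking-constraint updates and multiplier-based releases; finite
  termination for strictly convex objectives, iteration-capped with the
  KKT residual always reported.
* Compliant-tendon equilibria are bracketed before root-finding; an
  unbracketable balance raises a classed error rather than returning a
  clamped value.
* Degenerate inputs raise classed conditions
  (`mousegait_range_violation`, `mousegait_slack_tendon`,
  `mousegait_degenerate_frame`, ...) so callers can distinguish contract
  violations from numerics.

# Known limitations

* Mono-articular synthetic muscle paths (see above) — the largest
  source of difference from the deposited model, surfacing as elevated
  knee/ankle reserve use.
* 2-D sagittal dynamics with a decoupled hip-adduction balance; no
  long-axis rotations, no MTP joint, no wrapping surfaces or ligaments.
* GRF is always prescribed, never emergent (no contact model).
* The muscle-driven forward simulation drifts from the measured
  kinematics (as unconstrained forward dynamics does in the source);
  its work estimates are a sensitivity comparison, not a validated
  reconstruction.
* The printed MTU table is two rows short of the deposited model's 44;
  the package carries the 42 printed rows.
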