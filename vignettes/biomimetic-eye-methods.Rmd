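---
title: "Models and methods behind bioeye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bioeye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bioeye` simulates a tendon-driven robotic eye with six independent
motor-driven cables, generates saccades for it by optimal control, and
analyses the resulting three-dimensional movements the way oculomotor
physiology analyses real eye movements. This vignette documents the models,
the choices behind every tunable default, and what the package's tests do
and do not establish.

## Orientation algebra

Eye orientations are Euler-Rodrigues rotation vectors
`r = tan(theta/2) * n` (units "rad/2") in a right-handed head-fixed frame:
x forward along the reference gaze line (clockwise torsion positive), y
leftward (downward rotation positive), z upward (leftward rotation
positive). Gaze angles used by the analysis layer are
`azimuth = -2 atan(r_z)` and `elevation = -2 atan(r_y)`, in degrees with
rightward/upward positive. The angular velocity about the momentary
rotation axis and the coordinate velocity (the time derivative of `r`) are
related by the exact non-commutative maps

    omega = 2 (rdot + r x rdot) / (1 + |r|^2)
    2 rdot = omega + omega x r + (omega . r) r

which `omega_from_rdot()` / `rdot_from_omega()` implement and the test
suite verifies against an independent unit-quaternion oracle to 1e-10.
Compositions of rotations (`rot_compose()`, `rot_between()`) error out at
the 180-degree singularity instead of regularizing it; the oculomotor
workspace stays below roughly 50 degrees, two orders of magnitude away
from the singular set, so a hard failure is the correct behaviour.

## The plant

The globe is a rigid sphere (12 mm radius) rotating about its fixed centre
under three torques: the sum over six cables of
(insertion point) x (tension * pulling direction), a single viscous
damping term standing in for the sliding supports of the physical
prototype (no Coulomb friction), and the gyroscopic term of an anisotropic
inertia tensor. Cables run as straight segments from their (rotating)
insertions to fixed anchors -- the nasally displaced annulus for the four
recti, anterior-nasal pulley points for the two obliques -- with no globe
wrapping and no side-slip constraint. Tension is a pull-only linear spring
on (path stretch + commanded shortening), clamped at zero: a cable can go
slack but can never push.

The coordinate tables of the original prototype are not public, so the
default geometry is a calibrated stand-in digitized from standard
human-eye proportions and then adjusted, as a deliberate calibration, until
the optimal-control behaviour reproduced the qualitative saccade phenomena
the package is built to study:

* polar insertion angles LR 75 / MR 70 / SR 45 / IR 43 degrees, recti
  origins at x = -35 mm displaced 2-4 mm nasally (this displacement is what
  makes the static LR tension at straight-ahead fixation slightly exceed
  the MR tension, and tilts the fitted orientation plane);
* oblique pulleys at (5, 10, 11) and (6, 10, -11) mm;
* stiffness 0.25 N/mm, damping 0.8 N mm s/rad, pretension 0.6 N, inertia
  diag(0.48, 0.42, 0.45) kg mm^2 (mild anisotropy: camera payload; an
  isotropic globe is one argument away).

The calibration targets were: a human-like main sequence (peak velocities
of a few hundred deg/s, duration slopes of 2-3 ms/deg), overdamped
overshoot-free step responses, a convex total-cost profile over the
duration grid, and vertical saccades at least as fast as horizontal ones
at matched amplitude. These values are calibration, not measurements.

**Integration.** The fast eigenvalue of the damped dynamics
(damping/inertia, about 1.8e3 /s) makes first-order explicit schemes
marginal at the 1 ms sampling step, so the propagator is classical RK4 at
1 ms with zero-order-hold controls. The suite checks agreement with a
half-step reference to better than 0.1% over 100 ms. The factor 1000 in
`I(r) wdot = 1000 tau - w x (I(r) w)` converts the mixed units
(N mm, kg mm^2) to rad/s^2.

**Holding commands.** All control signals are expressed relative to the
minimum-norm command that holds the straight-ahead fixation with zero net
torque. `fixation_command()` solves the same problem at any orientation;
when the unconstrained minimum-norm solution would drive a cable below the
slack floor (which happens at the extreme corners of the +-0.3 rad/2 goal
range), the violating cable is pinned at the floor and the rest re-solved.

## The optimal controller

A saccade to goal `x_G = (0, G_y, G_z, 0, 0, 0)` -- zero target torsion,
zero final velocity -- is found in two loops. The inner loop, for a fixed
candidate duration `D`, minimizes

    J_MOV = lambda_a * J_A + lambda_d * J_D + lambda_e * J_E

where `J_A = |r(D) - r_G|^2 + w_omega |omega(D)|^2` (squared endpoint
error; the velocity term enforces stopping), `J_D = D / (1 + gamma D)` (a
hyperbolic reward discount: increasing, concave, zero at zero), and
`J_E = sum_i integral (du_i/dt)^2 dt` (motor kinetic energy; the jump from
the pre-movement holding command is charged too, so impulsive commands are
penalized like any other motor motion). Controls are per-muscle knots
every 10 ms with linear interpolation, seeded on the straight line between
the start and goal holding commands, bounded at +-8 mm, and refined by
L-BFGS-B; the gradient is computed by forward differences inside the
compiled objective. The outer loop evaluates the duration grid 30-210 ms
in 20 ms steps (warm-starting each duration from the previous solution
resampled in normalized time) and keeps the argmin, ties toward shorter
durations.

The weights are not physical constants but unit conversions plus a
preference scale. The defaults `lambda_a = 2e4`, `lambda_d = 10`,
`lambda_e = 2e-3`, `w_omega = 2e-3`, `gamma = 2 /s` were calibrated once,
together with the plant, so that `J_MOV(D)` is convex with an interior
minimum for 10-30 degree saccades (`bioeye calibrate` prints the profile),
endpoint errors stay well below a degree, and the selected durations grow
roughly affinely with amplitude. Because torsion enters the accuracy cost
only through the goal's `r_x = 0`, any plane-like confinement of the
simulated orientations is an emergent behaviour, not a constraint.

Two known limitations of this calibration are worth stating plainly.
First, the pulse-step structure of the optimized commands -- an agonist
transient exceeding its final holding level, mirrored by the antagonist --
is pronounced for small and medium saccades (3-10 degrees) but fades for
larger ones, where the selected duration is long relative to the plant's
time constant and a ramp-to-step is already optimal. Second, the vertical
speed advantage at matched amplitude is a few percent, smaller than in
monkey data; it appears where horizontal and vertical movements select the
same grid duration and the vertical plant, having four pullers, shapes a
slightly peakier profile.

## The surrogate

`generate_prbs()` drives each muscle independently between two levels
(default +-1.5 mm, spanning the command range of saccades up to about 20
degrees) with exponentially distributed hold times (mean 60 ms, minimum
10 ms); the averaged periodogram is flat within +-3 dB below half the mean
switch rate. `train_surrogate()` fits a NARX-style one-step model of the
state increment on two delay taps of state and command, z-scored, by
teacher forcing; `surrogate_rollout()` then runs it closed-loop on its own
feedback. Accuracy is reported as closed-loop NRMSE per state channel on a
held-out contiguous block.

The default readout is *linear* in the taps. On this plant that linear
NARX reaches < 4% held-out closed-loop NRMSE, while small single-hidden-
layer networks (8-16 units, BFGS) fit the one-step map well but are
unstable under their own feedback at desk-scale data; `hidden > 0` remains
available. The optimizer accepts the surrogate in place of the plant
(`optimize_for_duration(..., surrogate = )`); the suite checks that
optimizing against the surrogate and replaying on the plant moves the
endpoint by less than a degree. The direct-on-plant path is the default
everywhere: with the compiled objective it is fast enough that the
surrogate is an accuracy trade, not a necessity.

## Paradigms and stimulation

Three seeded paradigms generate data sets: `zero_initial` (all saccades
from the origin; uniform 2D goals on the +-0.3 rad/2 square, so diagonal
amplitudes reach about 46 degrees), `continuous` (chained starts; the
amplitude of each movement is the rotation angle of the relative rotation
carrying start to goal), and `horizontal_continuous` (targets on a 0.012
rad/2 grid along the horizontal meridian). Desk-scale sizes are 30/50/30
saccades -- a full run in minutes on one core -- with `full = TRUE`
switching to the campaign sizes 199/298/202.

`stimulate_muscle()` emulates motor-nerve micro-stimulation: the eye holds
an eccentric fixation, a Gaussian pulse (FWHM 21 ms) is added to one
muscle's command, and the torsion accumulated from pulse onset to the
*turning point* of the evoked movement (maximum orientation displacement)
is regressed on the initial eccentricity. The turning point replaces a
speed-threshold offset because this plant is elastic: after the pulse the
restored holding command pulls the eye straight back, and integrating
through the passive return would cancel the torsion the stimulation
actually produced. The function's default pulse amplitude is the peak
agonist drive of a 10-degree optimal saccade (about 1.2 mm); the package's
own experiments use 5 mm, which evokes 10-20 degree movements comparable
to published stimulation traces -- at 1.2 mm the evoked movement is about
2 degrees and the induced torsion sits inside the orientation-plane
width, so no plane violation can be resolved. The reference plane for that
comparison is fitted to the pre-stimulation vertical movements, which is
how the experimental design defines it.

On this plant, LR and MR stimulation produce torsion that is strikingly
linear in the initial vertical eccentricity (r^2 > 0.999) with opposite
signs for the two muscles, and large enough at 5 mm pulses to leave the
fitted plane by more than three plane widths: the plane-like behaviour of
the optimized saccades is implemented by the controller, not by the
mechanics. SO stimulation from horizontal eccentricities evokes a large,
essentially position-independent cyclo-torsion: the tight linear position
dependence that recti stimulation shows does not materialize for the
oblique in this geometry (its linear r^2 is about 0.76, dominated by a
constant offset). `stimulate_so()` reports the regression either way.

## Analysis conventions

* Amplitude `R = sqrt(dAz^2 + dEl^2)` and direction `Phi = atan2(dEl,
  dAz)` from onset/offset gaze angles; optimizer saccades use `[0, D]`,
  free traces a 20 deg/s threshold with hysteresis.
* Peak velocity is `max |omega|` in deg/s (switchable in principle to
  coordinate-velocity measures; component peaks use gaze-angle
  derivatives).
* Curvature: translate to the origin, rotate the chord onto the positive
  horizontal axis, take the signed maximum perpendicular deviation over
  the chord length, sign flipped so clockwise is positive; straight below
  0.03, curved above 0.15.
* The orientation plane is fitted by ordinary least squares of `r_x` on
  `(r_y, r_z)` through the origin (the regression form of the plane
  definition, not total least squares); its width is the residual sd in
  rad/2 with the angular equivalent `2 atan(sigma)` reported alongside.
  Note that for a width quoted as 0.075 rad/2 that conversion gives 8.6
  degrees, whereas 0.86 degrees corresponds to 0.0075 rad/2 -- when
  comparing against published width figures, check which scale is meant,
  as the two differ by exactly the factor ten.
* The position-gain regression z-scores peak velocity, amplitude and
  initial orientation; the orientation regressor is signed against the
  movement direction (contralateral start positive), so its positive
  coefficient means centripetal saccades are faster. Nested models are
  compared by the F test, amplitudes below 6 degrees excluded.
* Within-saccade component correlations sign-align the horizontal and
  vertical velocity profiles with the movement quadrant, so perfectly
  coupled components score +1 in every direction; "oblique" means at
  least 20 degrees from the nearest cardinal direction.

## What the synthetic data do and do not show

Every data set this package analyses is produced by its own simulator
under the frozen calibration above. Passing tests therefore demonstrate
internal consistency -- the controller really does produce accurate,
main-sequence-obeying, nearly straight, plane-confined movements with
agonist/antagonist organization on *this* plant -- and faithful
implementations of the published analysis formulas, which the suite
verifies on closed-form fixtures. They do not demonstrate anything about
a physical prototype (motor dynamics, cable friction and camera-cable
stiffness are absent), nor that the specific fitted numbers (plane tilt,
saturation velocity) transfer beyond this geometry: those depend on
supplementary plant constants that are not public, and the package's
values are reproducible stand-ins, not re-measurements. Problem sizes in
the tests (30-saccade runs, 2e4 ms identification records, 13-onset
stimulation series) are the package's desk-scale defaults; the paradigm
functions scale to the full campaign sizes with one flag.
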