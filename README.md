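# bioeye

Saccade generation and 3D kinematic analysis for a six-tendon biomimetic
robotic eye.

The human eye is rotated by six extra-ocular muscles, but voluntary gaze
uses only two degrees of freedom: with the head still, the torsion of the
eye is fixed by gaze direction, and 3D eye orientations expressed as
rotation vectors lie in a plane (Listing's law). Whether that constraint --
and the other saccade regularities: the nonlinear main sequence, straight
oblique trajectories, pulse-step motor commands, agonist/antagonist muscle
pairing -- is imposed by neural control or by the mechanics of the eye
plant is a long-standing question in oculomotor physiology. `bioeye`
provides a self-contained computational testbed for it: a tendon-driven
rigid-body eye with human-like muscle insertions, an optimal controller
that generates its saccades, and the complete analysis toolkit used on
real eye-movement data.

The package is aimed at computational neuroscientists and robotics
researchers who want to regenerate and quantify these phenomena from
scratch on a desktop, and at anyone needing a careful R implementation of
3D eye-movement analysis (rotation-vector kinematics, Listing-plane fits,
main-sequence and curvature metrics) for their own gaze recordings.

## The model in brief

* **State**: Euler-Rodrigues rotation vector `r = tan(theta/2) n` (rad/2)
  plus angular velocity `omega` (rad/s), related to the orientation rate by
  `omega = 2 (rdot + r x rdot) / (1 + |r|^2)`.
* **Plant**: Newton-Euler rigid body, `I(r) wdot = tau - w x I(r) w`, with
  the net torque summed over six pull-only elastic cables (linear springs
  with pretension, slack-clamped at zero) whose pulling directions follow
  the rotating insertions; viscous damping; RK4 integration at 1 ms.
* **Controller**: for each candidate duration `D` in {30, 50, ..., 210} ms,
  find per-muscle commands minimizing
  `J_MOV = lambda_A J_A + lambda_D J_D + lambda_E J_E`
  (squared endpoint error with a stopping term; hyperbolic duration
  discount `D/(1+gamma D)`; motor energy `sum (du/dt)^2 dt`), then keep the
  duration with minimal total cost.
* **Surrogate (optional)**: a NARX-style one-step model identified from
  pseudo-random binary (PRBS) excitation can stand in for the plant inside
  the optimizer.
* **Analysis**: accuracy regressions, main sequence (`D = e + f R`,
  `V_pk D = k + m R`, saturation `m/f`), trajectory curvature, Listing-plane
  fits `r_x = alpha r_y + beta r_z`, component cross-coupling against the
  common-source prediction, position-dependent velocity gains, muscle-pair
  correlations, and simulated muscle-stimulation experiments.

## Worked example

Generate a 15-degree rightward saccade with the default plant and inspect
it:

```r
library(bioeye)

plant <- eye_plant()
sac <- optimal_saccade(plant, saccade_goal(0, -tan(7.5 * pi / 180)))
print(sac)
#> <optimal_saccade> amplitude 15.0 deg, D_opt = 90 ms, J_MOV = 1.0198
#>   endpoint error 0.01 deg; sub-costs J_A=0.0003 J_D=0.7627 J_E=0.2568

m <- saccade_metrics(sac$trajectory, D = sac$D_opt)
round(c(R = m$R, Phi = m$Phi, V_pk = m$V_pk), 1)
#>     R   Phi  V_pk
#>  15.0   0.0 240.3
```

The controller picked a 90 ms duration off its grid, landed within a few
hundredths of a degree of the target, and produced a single-peaked
velocity profile with a 240 deg/s peak -- on the human main sequence for
this amplitude. A small chained-paradigm run and its population analyses:

```r
ds <- run_continuous(plant, paradigm_config("continuous", n = 10, seed = 1))
accuracy_regression(ds)
#> <accuracy_fit> n=10
#>   azimuth  = +0.001 + 1.000 T_H (r^2 = 1.0000)
#>   elevation= +0.006 + 1.000 T_V (r^2 = 1.0000)
#>   errors: H 0.00 +/- 0.01 deg, V 0.01 +/- 0.01 deg

fit_listing_plane(ds)
#> <listing_fit> r_x = +0.0069 r_y -0.0044 r_z  (n=1530, r=0.204)
#>   width sigma = 0.00493 rad/2 (0.565 deg), tilt 0.39 deg about z
```

Endpoint gains are 1.0 with r^2 > 0.99 (the movements are accurate), and
the 3D orientations stay confined to a plane less than a degree wide even
though no torsion constraint is imposed anywhere -- the plane emerges from
the optimal control. A stimulation experiment shows that the plant itself
does not implement that plane: pulsing the lateral rectus from different
elevations drives torsion linearly out of it,

```r
stimulate_muscle(plant, stimulation_config("LR", amplitude = 5))
#> <stimulation_result> LR pulse (5.00 mm, FWHM 21 ms), 13 onsets
#>   delta_rx = 0.06753 * r_on +0.0017   (r^2 = 0.9999)
```

A thin command-line wrapper over the same functions is installed as
`exec/bioeye` (subcommands `simulate`, `optimize`, `paradigm`,
`stimulate`, `analyze`, `calibrate`).

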