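# pendknee

Quantifying post-stroke knee spasticity from ordinary video: pendulum-test
analysis of pose-estimation keypoint trajectories, with the
method-agreement statistics needed to validate a camera against an
electronic goniometer.

## The problem and who this is for

In the pendulum test a supine patient's lower leg is released from full
knee extension and swings freely; increased muscle tone (spasticity) damps
the decaying oscillation of the knee angle. Markerless human pose
estimators (2D estimators emitting 17 COCO keypoints with confidences, 3D
estimators emitting the same landmarks in space, both at 30 fps) make the
test feasible with nothing but a smartphone. This package is for
rehabilitation researchers and biomechanists who need to

* turn keypoint files into sagittal knee flexion angle traces,
* extract the standard pendulum parameters from those traces, and
* quantify how well a camera-based system agrees with a reference device
  and with clinical Modified Ashworth Scale (MAS) ratings.

## The quantities at the core

With u the hip-to-knee vector and v the knee-to-ankle vector, the knee
angle is `theta = arccos( u.v / |u||v| )` (0 deg = full extension). For 3D
input, u and v are first projected into the sagittal plane: the plane's
unit normal is `n = um x vm / |um x vm|` with um, vm body-midline vectors,
and `uh = u - (u.n)n`, `vh = v - (v.n)n` enter the same formula. Traces
are smoothed with a third-order Savitzky-Golay filter.

From the smoothed angle-time curve, with `theta_start` the release angle,
`theta_rest` the settled resting angle and e1, e2, e3 the first three
swing extrema:

| Landmark | Definition |
|---|---|
| A0 | release-to-rest distance, abs(theta_start - theta_rest) |
| A1 | first-swing excursion, e1 - theta_start |
| A3 | second-swing offset from rest, abs(e2 - theta_rest) |
| A4 | second-swing cycle excursion, abs(e3 - e2) |

and the clinical parameters are **P1 = A1/A0** (normalized relaxation
index), **P2 = A3** (first maximum of oscillation, degrees) and
**P3 = A4/A3** (relaxation index at half swing). For a linear damped
oscillator with damping ratio zeta, successive extrema decay by
`r = exp(-pi zeta / sqrt(1 - zeta^2))` per half cycle, so P1 = P3 = 1 + r
exactly -- the closed form the built-in simulator uses as an oracle.

The agreement battery mirrors standard method-comparison practice:
Bland-Altman bias and 95% limits of agreement with a proportional-bias
regression of difference on mean; the two-way random-effects **consistency
ICC** `(MSR - MSE) / (MSR + (k-1) MSE)` with exact F-based confidence
bounds; paired affected-vs-unaffected t-tests with the raw mean difference
and the standardized paired effect size; Spearman rank correlation (midrank
ties) of each parameter with MAS after Tukey-fence (1.5 IQR) outlier
screening; and a Shapiro-Wilk normality gate that annotates rather than
blocks.

## Worked example

Simulate one spastic trial, render it as noisy 2D keypoints, and recover
the parameters:

```r
library(pendknee)

model <- pendulum_model(zeta = 0.3, theta_rest = 70, theta_release = 0)
trace <- simulate_trace(model)                 # ground-truth swing
kp    <- render_keypoints(trace, body_geometry("right"),
                          dims = 2, noise_sd = 2, seed = 1)
est   <- knee_angle_2d(kp, "right")            # angles from keypoints
lm    <- swing_landmarks(smooth_trace(est))
pendulum_parameters(lm)
#> <pendulum_parameters> P1=1.376 P2=9.24 deg P3=1.353
closed_form_extrema(model)$half_cycle_ratio + 1   # analytic P1 = P3
#> [1] 1.372326
```

The estimate from 2-pixel-noise keypoints lands within 0.01 of the
analytic 1 + r. A whole synthetic study (20 subjects, both limbs, 5 trials
per limb, three recording channels per trial) runs the same way:

```r
out    <- simulate_cohort(cohort_spec(), "cohort_dir", seed = 1)
trials <- analyze_cohort(out$trial_table)
rep    <- study_report(trials)
rep$limbs[rep$limbs$parameter == "P1" & rep$limbs$device == "goniometer", ]
#>       device parameter mean_affected ... effect  d_paired  p_value
#>   goniometer        P1          1.31 ... -0.414     -3.09  2.35e-11
```

Affected limbs show lower P1 than unaffected ones (more damping), the
cross-device ICC for P1 exceeds 0.99 on this clean synthetic cohort, and
P1 correlates negatively with the MAS level that drives the simulated
damping. The `clinical_limb_summary()` table ships the published group
means of a 20-patient clinical validation cohort, and
`limb_effect_table()` reproduces its between-limb effect column from
those means.

There is also a thin command-line wrapper at `inst/cli/pendknee.R`
(`angles`, `params`, `study`, `simulate-cohort` subcommands; exit code 2
for input errors, 3 for degenerate traces).

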