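---
title: "Pendulum-test analysis of knee spasticity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pendulum-test analysis of knee spasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pendknee)
```

## The measurement problem

The pendulum test indexes knee muscle tone by releasing the supine
patient's lower leg from full extension and recording the decaying swing
of the knee angle. A spastic limb damps the oscillation: the first swing
is cut short and later swings shrink faster. Markerless pose estimators
turn smartphone video into per-frame skeleton keypoints, so the test can
be scored without goniometers or marker-based motion capture — provided
the keypoint-to-parameter pipeline is trustworthy. This package is that
pipeline, plus the statistical battery used to establish trust (agreement
with a reference device, separation of affected from unaffected limbs,
correlation with clinical MAS ratings), plus a simulator that makes every
stage verifiable against closed-form ground truth.

## From keypoints to a knee angle

The knee angle is the angle between the hip→knee vector $\vec u$ and the
knee→ankle vector $\vec v$:
$\theta = \arccos\!\big(\vec u \cdot \vec v / |\vec u||\vec v|\big)$,
so $\theta = 0^\circ$ at full extension and grows with flexion. The
arccos argument is clamped to $[-1, 1]$: on collinear frames floating
point can overshoot by a few ulps and a domain error there would be
spurious. Angles are invariant to translation, uniform scaling and the
y-down image convention, so 2D pixel coordinates are used as-is.

For 3D input the two segment vectors are first projected into the
sagittal plane to discard mediolateral wobble. The plane is spanned by
two body-midline vectors and its unit normal is their cross product,
$\vec n = \vec u_m \times \vec v_m / |\vec u_m \times \vec v_m|$; the
in-plane components $\vec u_h = \vec u - (\vec u\cdot\vec n)\vec n$ and
$\vec v_h$ enter the same arccos formula.

**Choice of midline vectors.** The COCO-17 landmark set offers no
explicit anterior-posterior landmark pair, and which midline vectors to
use is genuinely open. We take $\vec u_m$ = mid-shoulder→mid-hip
(longitudinal) and $\vec v_m$ = mid-hip→nose. Both lie in the anatomical
midsagittal plane — the nose sits anterior to the shoulder–hip line — so
their cross product is the mediolateral direction and the projection
keeps exactly the sagittal motion. The tempting alternative, the
hip-to-hip axis for $\vec v_m$, does *not* span the sagittal plane with
$\vec u_m$: their cross product is the anterior-posterior axis, and for a
supine subject projecting that component out flattens the swinging shank
onto the horizontal plane and destroys the flexion angle entirely. That
variant is still available as `plane.midline = "hip_axis"` for
sensitivity analysis; the default is `"nose"`. The plane is estimated per
frame by default (the pelvis can shift slightly during trials);
`plane.mode = "averaged"` uses one sign-aligned mean normal when noise
robustness matters more.

Frames whose hip, knee or ankle confidence falls below 0.3 (2D only) are
treated as missing and filled by linear interpolation before smoothing,
keeping the sampling grid uniform. The 0.3 gate is a conventional
pose-estimation default; whether and how the original clinical analyses
gated low-confidence frames is not documented, so the gate is exposed as
`conf.min_confidence`.

## Smoothing

Traces are smoothed with a third-order Savitzky–Golay filter
(`signal::sgolayfilt`), which preserves peak and trough amplitudes far
better than a moving average — essential here, since the landmarks *are*
peak amplitudes. The window length is not dictated by the method; the
default of 11 frames (≈ 0.37 s at 30 fps) suppresses keypoint jitter
while leaving the ~1 Hz swing intact, and is exposed as
`smoothing.window_frames`. Polynomials up to degree 3 pass through the
filter unchanged (to 1e-9°, verified in the test suite), including at the
edges, where the filter's off-center fits apply.

## Landmarks and parameters

On the flexion-positive axis the leg's physical lowest point (maximal
flexion) is a local *maximum* of $\theta$ and its highest point a local
minimum; that mapping resolves every "highest/lowest" phrase in the
landmark definitions consistently with the familiar decaying-oscillation
curve. With $\theta_{start}$ the release-frame angle, $\theta_{rest}$
the settled resting angle, and $e_1, e_2, e_3$ the first three interior
extrema (flexion peak, extension trough, flexion peak):

$$A_0 = |\theta_{start} - \theta_{rest}|,\quad
  A_1 = e_1 - \theta_{start},\quad
  A_3 = |e_2 - \theta_{rest}|,\quad
  A_4 = |e_3 - e_2|$$

$$P_1 = A_1/A_0,\qquad P_2 = A_3,\qquad P_3 = A_4/A_3.$$

Notes on deliberate choices:

* The landmark naming scheme in the clinical literature jumps from
  $A_1$ to $A_3$; no $A_2$ exists and none is invented.
* $P_2$ is *named* "first maximum of oscillation" but *defined* through
  $A_3$, the second-swing offset; the definition wins.
* $A_0$ uses the release-frame angle rather than a separate pre-release
  static measurement, which the recording itself cannot provide.
* The resting angle is the mean of the final 1.0 s of the trace
  (`rest.tail_seconds`), where oscillation has decayed. If the tail
  variance exceeds 5 deg² a typed warning flags the trace as possibly
  unsettled; the value is still returned and study-level code records the
  flag.

**Extremum detection.** Turning points are sign changes of the first
difference; plateaus take their first frame (determinism). Wiggles are
pruned against a prominence threshold (`extrema.min_prominence_deg`,
default 1.0° — above numerical ripple, below post-smoothing pose jitter)
by three alternation-preserving moves iterated to a fixed point: leading
extrema that barely depart from the release value are dropped; trailing
extrema are truncated when their excursion from the *previous turning
point* falls below threshold (judging the tail against the settled trace
end instead would swallow small genuine second swings in strongly damped
limbs); and interior adjacent pairs closer than the threshold (noise
wiggles riding on a swing) are removed pairwise. The release sample is
then prepended as the initial extremum. For noiseless simulated traces
the threshold's noise-rejection job vanishes and the verification suites
lower it to 0.05°.

Traces with fewer than three interior extrema — severely spastic or
overdamped limbs with no second swing — raise a typed error carrying the
landmarks that *could* be measured ($A_0$, and $A_1$ when a first peak
exists), so cohort-level code counts exclusions explicitly; `P3` is
likewise left undefined (never 0/0) when $A_3 = 0$.

## The damped-oscillator simulator

`simulate_trace()` samples
$\theta(t) = \theta_{rest} + (\theta_{release}-\theta_{rest})\,
e^{-\zeta\omega_n t}\big[\cos\omega_d t +
\tfrac{\zeta}{\sqrt{1-\zeta^2}}\sin\omega_d t\big]$
with $\omega_d = \omega_n\sqrt{1-\zeta^2}$ (matching closed forms for
$\zeta \ge 1$). Extrema sit exactly at $t_k = k\pi/\omega_d$ with
amplitudes $A r^k$, $r = e^{-\pi\zeta/\sqrt{1-\zeta^2}}$, giving
closed-form landmarks and the identity $P_1 = P_3 = 1 + r$ — the oracle
`closed_form_extrema()` that the landmark code is tested against (and
never shares code with).

`render_keypoints()` embeds a trace in a fixed supine skeleton (thigh
0.45 m, shank 0.43 m, hip axis 0.9 m above the floor) and emits either 3D
world coordinates or an orthographic 2D camera at 500 px/m — lateral
(angle-preserving, so exact oracles exist) or 45° oblique
(foreshortened by a hand-computable amount). Orthographic rather than
perspective projection is deliberate: the clinical pipelines being
emulated apply no camera model, and exact angle preservation in the
lateral view is what makes the renderer an oracle rather than another
approximation.

`simulate_cohort()` reproduces the study layout: 20 subjects, one
affected limb each (MAS level drawn from {0, 1, 1+, 2}, probabilities
0.1/0.3/0.3/0.3, "1+" stored as ordinal 1.5), unaffected limbs at MAS 0,
5 trials per limb, each trial recorded simultaneously by three channels
sharing one true swing: a goniometer CSV (noise SD 0.25° — the reference
device is treated as near-truth), lateral 2D keypoints (1.5 px noise) and
3D keypoints (4 mm noise). Damping follows MAS through
ζ-means 0.10/0.25/0.35/0.45 (SD 0.05 per trial), so higher MAS ⇒ more
damping ⇒ lower P1 by construction. The ζ draws are truncated to
[0.05, 0.95]: below 0.05 a 12 s recording has not settled and the
resting-angle estimate's own precondition (a decayed tail) fails by
construction. Subject-level natural frequency is N(5.5, 0.4) rad/s
(~0.9 Hz) and resting angle N(70°, 5°); release angles sit near full
extension (N(2°, 1°), truncated at 0).

What the generator deliberately does **not** emulate: perspective and
lens distortion, occlusion and tracking failures, pose-estimator bias
(its noise is unbiased Gaussian), voluntary muscle activity or the
velocity-dependent spastic catch (a reflex-torque variant would lack a
closed form and thus an exact oracle), and inter-subject anatomy beyond
frequency and rest-angle variation. Passing the synthetic suites
therefore demonstrates correctness of the *computations*, not clinical
performance of pose estimation; the ζ→P1 scale is a synthetic
calibration (unaffected P1 ≈ 1.7 here vs ≈ 1.1 in clinical goniometry),
chosen for clean oracles rather than clinical realism, which is why the
cohort-level acceptance checks are ordering and agreement properties
rather than absolute parameter values.

## Agreement statistics

* **Bland–Altman**: bias = mean(y − x), limits = bias ± 1.96 SD;
  proportional bias by OLS of difference on pairwise mean (slope p-value
  two-sided).
* **ICC**: the literature this implements labels its model "ICC(2,1),
  consistency type". The canonical two-way random single-rater form is
  absolute-agreement, while the *consistency* form is
  $(MS_R - MS_E)/(MS_R + (k-1)MS_E)$, excluding the rater main effect
  from error. The consistency formula is what `icc_consistency()`
  computes, matching the stated type; confidence bounds use the exact
  F-interval for that form. Negative estimates are reported as-is and
  flagged, never clamped.
* **Paired limb comparison**: two-sided paired t on subject-level trial
  means; the `effect` column reports the *raw mean difference* because
  that is the convention of the summary tables this reporting reproduces
  (their printed "effect sizes" equal mean differences, e.g.
  0.74 − 1.11 = −0.37), while the standardized `d_paired` =
  mean(d)/SD(d) is emitted alongside.
* **Spearman vs MAS**: midrank ties (MAS is heavily tied), asymptotic
  two-sided p. Outliers in the parameter values are first removed by the
  Tukey fence (1.5 × IQR, quartiles by linear interpolation of order
  statistics — type 7; fence membership at small n depends on the
  convention, hence it is pinned). Screening is applied per
  device × muscle stratum; whether the original analyses screened
  per-stratum or globally is unstated, and per-stratum is the
  conservative reading of "per analysis".
* **Shapiro–Wilk gate**: annotates downstream analyses at α = 0.05,
  never blocks them. No multiplicity correction anywhere, matching the
  analysis being reproduced.

## Verification strategy and problem sizes

The test suite pits every computation against an independent oracle:
hand-computed geometry (0°/45°/90° poses, a hand-evaluated 3D
projection), brute-force turning-point scans, explicit sums-of-squares
ANOVA for the ICC (agreement to 1e-10), Pearson-on-midranks for
Spearman, Monte-Carlo type-I error for the paired t (2000 null
replicates, n = 20 pairs), and the closed-form oscillator for landmarks
(ζ grid 0.05–0.6, 20 s traces at 30 fps, landmark agreement within 0.5°
and P1/P3 within 0.02 of 1 + r). The end-to-end check runs the default
20-subject cohort (600 trial files) through file I/O, kinematics,
landmark extraction and the full statistical battery, and asserts the
construction's qualitative signatures: affected mean P1 below unaffected
(paired p < 0.01), Spearman ρ(P1, MAS) < −0.5, goniometer-vs-pose ICC
for P1 > 0.8.

## Known limitations

* The 45° oblique 2D view is analyzed as-is; no perspective or
  view-angle correction is applied, so oblique 2D angles are biased by
  foreshortening (quantified exactly for the simulator's geometry in the
  tests). Lateral video is the supported 2D use case.
* The landmark extraction assumes the release frame is the first sample
  of the trace; recordings with a pre-release hold should be trimmed
  first.
* `P2` is an absolute angle and inherits every baseline and setup
  sensitivity the ratio parameters cancel; its weak performance in
  clinical validation is expected and not a defect of this
  implementation.
* MAS is ordinal and observer-dependent; the simulator treats it as the
  generative driver of damping, which is a convenience of construction,
  not a clinical claim.
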