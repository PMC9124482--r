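---
title: "Methods: flume foraging analysis for anchored garden eels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flume foraging analysis for anchored garden eels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardeneel)
```

Garden eels feed on drifting zooplankton while the posterior body stays
anchored in a sand burrow, so their foraging is governed by two external
variables — prey density and flow speed — and one behavioural one: how much
body they extend into the flow. This package implements the computational
chain used to study that trade-off in a recirculating flume: multi-camera
3D reconstruction of body points, strike kinematics and an
acceleration-based energy proxy, a segmented-cylinder drag model, and a
prey-flux foraging model, together with synthetic-data generators that make
every stage testable against known ground truth. This vignette documents
the models, the conventions, and the choices made where the design was
genuinely open.

## Coordinate frame and camera model

All 3D quantities live in the flume frame: origin at the burrow, x
streamwise with upstream positive, y lateral, z upward from the sand bed,
units metres (readers accept a cm dialect and convert on read). Each camera
is an 11-coefficient direct linear transformation (DLT),

$$u = \frac{L_1X + L_2Y + L_3Z + L_4}{D},\quad
  v = \frac{L_5X + L_6Y + L_7Z + L_8}{D},\quad
  D = L_9X + L_{10}Y + L_{11}Z + 1,$$

fit by linear least squares from at least six non-coplanar 3D–2D
correspondences (`dlt_calibrate()`), and inverted for a 3D point by
stacking two denominator-cleared equations per camera and solving the
overdetermined linear system (`dlt_reconstruct()`). No nonlinear
refinement and no lens-distortion model are applied: at flume working
distances (~1 m) and the sub-pixel noise levels of interest, linear DLT
triangulation is accurate to well under a millimetre, which is an order of
magnitude below the body-point localisation error of any tracker.

Numerical choices: the triangulation design matrix is column-normalised
before conditioning is assessed, and a condition number above 1e6 flags
the output as low confidence (rays essentially parallel — in practice only
near-coincident cameras trigger it). Observations carrying a `confidence`
below 0.6 (configurable) are dropped before triangulation, mirroring how
markerless-tracker likelihoods are normally screened. Calibration requires
the 3D points to span three dimensions; the smallest singular value of the
centred point cloud is checked against a 1e-10 relative floor.

## Strike kinematics

Strikes are taken from annotations (initiation and capture times, eye
positions, prey capture position); the study identified them visually, and
an optional speed-threshold detector (`detect_strikes()`, eye speed above
3x its rolling median for at least 3 frames) is provided purely as
plumbing for triage, not as a substitute for annotation. From an
annotation and the flow speed U, `strike_metrics()` computes:

- strike time $\Delta t$ and strike distance $|\Delta \mathbf{x}_{eye}|$;
- earth-frame speed (distance / time) and water-frame speed, obtained by
  subtracting the water drift $(-U\Delta t, 0, 0)$ from the eye
  displacement — the water moves downstream, i.e. toward negative x;
- reactive distance: brine-shrimp nauplii are poor swimmers, so the prey
  is back-advected from its capture position straight upstream,
  $x_{init} = x_{capture} + U\,\Delta t$, and the distance from the eye at
  initiation to that estimated prey position is reported.

At $U = 0$ the two frames coincide and the reactive distance reduces to
the strike distance; both identities are exercised as property tests.

## VeDBA

The vectorial dynamic body acceleration is computed from the 3D track of
the first black spot (nearest the body centre; the eye is used, with a
warning, only when the spot is absent):

$$a_i = (p_i - 2p_{i+1} + p_{i+2})\,\mathrm{fps}^2,\qquad
  \mathrm{VeDBA}_i = \sqrt{a_{x,i}^2 + a_{y,i}^2 + a_{z,i}^2}.$$

The three-point stencil is the second-order-accurate second difference,
recorded at the first index of each triple; a four-point one-sided stencil
differs negligibly at 60 Hz for the smooth motions involved but is not
identical, and the three-point form is the one implemented. The stencil
annihilates affine trends exactly (so a drifting but non-accelerating
track scores zero), and for a sinusoid of amplitude A and frequency f the
temporal mean converges to $(2/\pi)A(2\pi f)^2$ with an
$O(\mathrm{fps}^{-2})$ discretisation bias (~0.1% at 1 Hz and 60 Hz);
both facts serve as oracles in the tests. Tracks must be gap-free;
linear interpolation of missing frames is available behind an explicit
flag and marks the affected frames.

## Body length and the Q3 radius

Length out of the burrow is the arc length of the ordered body polyline
from the burrow origin to the snout; at least three points are required
(with only eye and spot the arc is undefined, and the analysis reports
"insufficient points" rather than guessing a chord). The feeding-area
radius is the third quartile of the per-frame length series — a value
between the mean (too small to cover the swept area) and the maximum
(larger than the area actually used). The quantile uses linear
interpolation between order statistics ($h = (n-1)p + 1$), delegated to
`stats::quantile(type = 7)` and configurable.

## Drag model

The body outside the burrow is divided into 7–8 cylindrical segments of
diameter 0.5 cm (`segment_body()`; arc-length-uniform resampling is
available, and segment lengths are measured along the body so resampling
preserves total length exactly). Each segment obeys the cross-flow
principle — only the velocity component normal to the segment axis,
$U_n = U\sin\theta$, generates pressure drag; skin friction of the axial
component is neglected, standard for slender-body decompositions:

$$Re = U_n d/\nu,\qquad F = \tfrac12\,\rho_w\,C_d(Re)\,d\,l\,U_n^2.$$

The drag coefficient uses the subcritical smooth-cylinder correlation
$C_d = 1 + 10\,Re^{-2/3}$, isolated behind `cylinder_cd()` and replaceable
by any function of Re; it warns beyond $Re = 2\times10^5$. Whole-body drag
is the sum over segments, and the whole-body coefficient normalises by a
reference area of diameter times total arc length, which makes a straight
body perpendicular to the flow recover the single-segment $C_d$ exactly
(projected frontal area is available as an alternative). Fluid defaults
are seawater at 25°C ($\rho_w = 1025$ kg m⁻³, $\nu = 9.7\times10^{-7}$
m² s⁻¹), matching the flume's temperature control.

Two counterfactual scenarios quantify what posture modulation buys:
(1) keep the posture and length observed at low flow and evaluate the
drag at the high flow speed; (2) keep a straight posture but shorten to
the length observed at high flow. The orientation of the straight
scenario-2 body is not dictated by the phenomenon itself; the package
defaults to the low-flow body's mean axis (burrow-to-snout direction,
falling back to vertical when degenerate), with a pure-vertical option,
because the mean axis preserves the animal's overall lean while removing
curvature — the quantity the scenario is meant to isolate.

## Foraging model and trial bookkeeping

The classical disk equation $F = a\rho/(1 + a\rho h)$ describes a type II
functional response; with the near-unity successful strike rates and short
handling times seen in these eels, the linear regime applies and feeding
is limited by prey flux $P = \rho U$. The package's feeding-area model
assumes all prey crossing a semicircle of radius L (the Q3 length), flat
side on the bed and lying in the cross-flow y–z plane, are captured:

$$F = P\,\frac{\pi L^2}{2}\quad\text{(per s; reported as } 60\,P\,\pi
L^2/2 \text{ nauplii min}^{-1}).$$

The semicircle is placed in the plane perpendicular to the flow since
that is the plane through which advected prey flux passes; the constant is
exactly $\pi/2$. A disk-equation fit (`fit_disk_equation()`, nonlinear
least squares with $h \ge 0$) is provided for density–rate data; data
confined to the linear regime leave h unidentifiable, which `glance()`
reports as a boundary fit rather than hiding it.

Trial bookkeeping follows the flume protocol: one trial lasts exactly one
water cycle (circuit length / flow speed, so the prey flux each eel sees
is fixed despite depletion). The circuit length, 5.6 m, is anchored by the
recorded 6720 frames spanning two trials at 0.10 m s⁻¹ and 60 Hz, which
forces the frame counts 4480, 3360 and 2688 at 0.15, 0.20 and
0.25 m s⁻¹ (frame counts round half to even). Released counts are
density times the 1.24 m³ flume volume; captures are released minus
recovered minus the mean control loss (≤5% of released, measured with no
eel present), clamped at zero with a warning when the correction exceeds
the apparent captures — the protocol does not define negative captures,
and zero is the only physically meaningful floor. Feeding rate is the
adjusted capture count per minute of cycle time. `study_design()`
enumerates the two crossed designs (5 eels x 5 densities x 2 speeds x 2
replicates, plus 5 eels x 4 speeds x 2 densities x 2 replicates; 180
trials).

## Synthetic scenes: what they emulate, and what they do not

The generators produce every input the pipeline consumes, deterministically
in a seed:

- `gen_eel_track()`: an 8-point polyline anchored at the origin whose base
  posture is a circular arc of specified arc length bending downstream
  (the arc's chord shortens as the bend grows, mimicking how extension
  shrinks with flow; the length-vs-speed mapping is a configuration table,
  `default_length_table()`, spanning 0.14 m at 0.10 m s⁻¹ down to 0.08 m
  at 0.25 m s⁻¹ — plausible extensions for 18–30 cm animals, chosen once
  as defaults, not fitted). Lateral sway is a sinusoid whose amplitude
  grows quadratically from zero at the burrow to the nominal amplitude
  (default 1 cm at 1 Hz) at the snout — the anchored tail moves least.
  Strikes are Poisson events (default 0.2 s⁻¹) in which the head darts
  straight at 0.2 m s⁻¹ toward a target sampled in the upstream-facing
  hemisphere within half a body length, and returns; ground-truth strike
  annotations and the per-frame length series are returned alongside the
  track.
- `gen_prey_particles()`: non-swimming tracers seeded as a spatial Poisson
  process in the 0.30 x 0.30 m cross-section and advected at $(-U, 0, 0)$;
  the count crossing the burrow plane in time T has mean $\rho U A T$,
  which ties the particle model to the prey-flux formula. An optional
  swimming-jitter term exists but is off by default.
- `gen_camera_obs()`: DLT projections of every body point through a rig of
  three pinhole-derived cameras (two side by side, one above, ~0.9 m from
  the burrow) plus isotropic Gaussian pixel noise.
- `gen_trial_counts()`: the feeding-area model run forward — Poisson
  captures with mean $\rho U (\pi L^2/2) T$, binomial control losses —
  used for parameter-recovery tests of the rate estimator.

These scenes deliberately omit turbulence, boundary-layer shear, prey
escape behaviour, body occlusion and tracker identity switches. Passing
tests therefore demonstrate that the estimators are correct for their
stated models and noise levels, not that a real tracker's output at these
noise levels is unbiased; with real video the dominant errors come from
digitisation, not from this geometry.

## Problem sizes and determinism

The test suite and the acceptance script run scenes of 3–10 s at 60 Hz
(a few hundred frames, eight body points, three cameras), 100-seed
Monte-Carlo loops for calibration/reconstruction noise, and 500 simulated
trials for feeding-rate recovery — sizes at which every Monte-Carlo
standard error involved is comfortably below the tolerance being checked
while the whole suite completes in about a minute. All generators restore
the caller's RNG state and record their seed; re-running any pipeline
stage with the same inputs and seed reproduces its outputs exactly (CSV
round-trips are value-stable at full double precision).

## Known limitations

- The drag correlation and reference area are conventions; whole-body drag
  comparisons are meaningful within one convention, and absolute drag
  percentages depend on them.
- The water-frame strike speed assumes a uniform free stream; near-bed
  velocity gradients are ignored.
- Length out of the burrow requires a multi-point polyline; two-point
  tracks (eye + spot) support kinematics and VeDBA but not length.
- The disk-equation fit cannot estimate handling time from linear-regime
  data — by construction of the data, not a defect of the optimiser.
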