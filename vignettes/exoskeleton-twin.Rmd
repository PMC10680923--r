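---
title: "Models and methods of the exoskeleton digital twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the exoskeleton digital twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exotwin)
```

`exotwin` models a robot-rodent interface in which a mouse, docked by a
chronically implanted headpost, drives a ceiling-mounted delta parallel
robot and a motorized goniometer by pushing against a milli-Newton force
sensor. This vignette documents the models behind each component, the
parameters that matter, the numerical choices, and what the synthetic
data generators do and do not emulate.

## Kinematic model

**Frames and conventions.** The base frame is right-handed with z up and
its origin at the fixed-platform center; the robot hangs above the arena
with arms reaching down. Joint angle zero means a horizontal proximal
link and positive angles rotate the link upward, so the actuated limit
range of [-90°, +45°] spans mostly-down postures. Angles are radians
internally and degrees at configuration and command-line boundaries.

**Delta robot.** Each arm is reduced to a planar two-link problem by
pulling the platform attachment back by the moving-platform radius.
Inverse kinematics solves the loop-closure equation per arm and takes
the *knuckles-out* elbow branch (elbow radially outboard of the
platform), the branch physical delta robots are assembled in; the branch
choice is deterministic, with ties broken toward the smaller angle.
Angles violating the joint limits are *flagged*, never clamped — a
controller must know it asked for an unreachable posture. Forward
kinematics intersects the three spheres of distal-link reach and keeps
the lower-z solution (the platform hangs below the arms). Both
directions close the loop to ≤ 1e-9 m, the tolerance the test suite
enforces on 1000 random round trips.

**Goniometer.** The three rotation axes meet at a common point 0.1 m
below the platform center, and the virtual pivot extends 0.25 m further.
The declared rotation order is pitch (about the mouse's lateral axis),
then roll, then yaw about the vertical through the pivot. Yaw is last
and pivot-aligned so that pure yaw spins the headstage without
translating the pivot — this matches a slip-ring yaw axis that supports
unbounded rotation, and yaw is therefore carried as an accumulated,
unwrapped angle. The exact axis nesting of the physical stage is not
public; this order is a documented assumption.

**Jacobian and singularities.** The delta block comes from
differentiating the loop closure (the vector method): `A pdot = B
thetadot` with `A` rows the distal-link vectors and `B` the projections
onto the knee tangents. The goniometer position columns are analytic
derivatives of the rotation chain; the orientation rows are the identity
on the goniometer angles. A configuration is flagged singular when the
6x6 condition number exceeds 1e6 (conservative for double precision,
configurable). At a stretched-arm singularity `B` collapses and the
delta block loses rank; inverse dynamics refuses configurations within
~30 µrad of a stretch, where torque amplification exceeds a thousandfold.

**Workspace.** `workspace_extent()` sweeps the three joints on a regular
grid (0.5° by default, ~20 million triples, evaluated by a vectorized,
chunked three-sphere intersection), bins reachable platform positions
into 2 cm z slices and 1 cm x-y occupancy cells, and reports per slice
the side of the largest centered, axis-aligned square whose every cell
is reached. Rasterization makes the answer conservative by up to one
cell. The home height of the pivot is not fixed by the design, so the
report scans z instead of asserting a single plane; the as-built
geometry covers the 80 x 80 cm design envelope near z ≈ -0.49 m.

## Dynamic model

The published machine cites a closed-form delta dynamics and a recursive
Newton-Euler goniometer model whose link inertias live in engineering
supplements. The twin instead uses the standard virtual-work surrogate:
every body is lumped into point masses —

* proximal link at its midpoint,
* distal link split between elbow and platform end (default split 0.5),
* platform, platform-end lumps, and the two upper goniometer stages
  riding with the platform,
* the third stage at half the pivot extension and the payload at the
  pivot, both rotating with pitch/roll,
* a configurable payload yaw inertia (0.002 kg m², a ~1.5 kg headstage
  at 4 cm gyration radius), the only yaw-axis inertia a point-mass model
  would otherwise lack.

Torques assemble by Jacobian transpose, `tau = sum_k m_k J_k^T (a_k - g)`,
with all positions, velocities, accelerations, and Jacobians analytic.
This makes the model exactly energy consistent: over any smooth
trajectory the integrated joint power equals the change in mechanical
energy to quadrature accuracy (the suite checks ≤ 1e-6 relative using
Simpson integration at 1 ms steps). The torque decomposition is defined
operationally — gravitational = ID(q,0,0), velocity = ID(q,qd,0) minus
gravitational, acceleration = the rest — so the three parts sum to the
total *identically*. Joint friction is deliberately absent: the physical
joints are built for low friction, and friction would break the
energy-balance oracle.

The default link masses (0.25 kg proximal, 0.15 kg distal, 0.8 kg
platform, 0.5 kg per goniometer stage) are documented estimates for the
carbon-fiber construction. They feed only feasibility margins: a
stationary hold with the 1.5 kg headstage and the design motion (0.2 m/s,
1 m/s² through the workspace center) stay far inside the motor limits,
and the margins survive any plausible re-estimate. Calibration targets
never depend on them.

## Admittance controller

Per mouse-relevant axis (x forward, y lateral, yaw), the discrete loop
runs at 100 Hz:

1. dead-band the force (±25 mN in x and y, ±0.3 mN m in yaw);
2. rotate the planar force into the mouse frame by the accumulated yaw;
3. `a = (F - c v) / m`, explicit-Euler to velocity and again to a target
   position — the literal "double integration" of the real 10 ms cycle
   (a higher-order integrator would misrepresent the hardware);
4. clip the forward command to ±16 cm/s, clamp it at ≥ 0 where the arena
   disables backward motion, zero y/yaw where a trajectory servo owns
   them.

Outside the band the dead-band *subtracts the threshold*, which keeps
the force-to-command map continuous; the alternative (pass the raw
force) is available as `deadband_mode = "passthrough"` but injects a
25 mN discontinuity that would excite the loop. The inner
velocity/current loops, tuned on hardware in the real machine, are
abstracted as one first-order lag (5 ms default). The virtual mass and
damping defaults (0.2 kg, 1.5 N s/m linear; 0.005 kg m², 0.02 N m s/rad
yaw) are *plausible-tuned* values: the published tuning is shown only
graphically, so no test asserts them — they only need to sit in the
stable, mouse-drivable regime.

## Loop model and bandwidth

The rendered ("apparent") admittance is modeled as
`Y_app = Y_virtual · D(s)` with `Y_virtual = 1/(m s + c)` and `D` the
product of a pure delay — half a cycle for the zero-order hold, one full
cycle of computation, plus the sensor delay — and the inner-loop lag.
Bandwidth is the lowest frequency where the *complex error*
`|Y_app / Y_virtual - 1|` reaches the -3 dB level `1/sqrt(2)`, refined
by bisection to 1e-3 Hz. This criterion was chosen over the naive
magnitude ratio because a pure delay has unit magnitude — a
magnitude-only criterion would be blind to the very delays the model
exists to study. The complex-error criterion has two clean limits that
the suite verifies: with no delay the crossing is exactly the inner-loop
corner frequency, and for a pure delay it is inversely proportional to
the delay. With the defaults (10 ms cycle, 10 ms sensor delay, 5 ms lag)
the bandwidth is ~3.9 Hz, and cutting the cycle from 50 ms to 10 ms
improves it ~3-fold — both consistent with the machine's reported
behavior. A -45° phase criterion is switchable for comparison.

## The virtual mouse

Free mouse locomotion is bout structured, and its velocity-acceleration
profiles arch: acceleration peaks while velocity is still rising, at
roughly 50-75% of the bout's peak. The generator emulates this with
skewed half-sine velocity pulses `v(t) = V sin^p(pi t / T)`; with the
default skew `p = 3` the acceleration peak falls at ~54% of `V`, and
`p = 1` recovers the plain half-sine (elliptical loop, peak acceleration
`pi V / T`). Heading-turn bouts (yaw half-sines of random sign) occupy
half the rest intervals; lateral intent is zero because a mouse mostly
travels along its heading.

Bout peak velocities and accelerations are log-normal. The log-means are
solved *in closed form* so the expected mean of the top 20% of draws
equals the calibration targets — 13 cm/s and 35 cm/s², the values
measured in freely behaving animals — using the truncated-lognormal mean
`E[X | X > q80] = exp(mu + sigma^2/2) * pnorm(sigma - z80) / 0.2`. Bout
duration follows from `T = g_p * pi * V / A`, which couples fast bouts
to short durations. The remaining parameters (log-sd 0.5, mean rest
~1.9 s, yaw bout 0.6 s at ~86 deg/s median) are realistic choices fixed
once; they shape peak counts, not the calibrated means. Everything is
reproducible under a seed, with the caller's RNG state restored.

The muscle model is a proportional velocity-error law with saturation
(`F = clip(gain (v_int - v_act), ±0.25 N)`). A pure proportional muscle
against damping `c` always undershoots by `c/(gain + c)`; the default
gain of 40 N/(m/s) represents a *trained* animal (~4% tracking error),
which is what makes closed-loop locomotion statistics match the free
intent — the same convergence the behavioral training produced. With
these defaults closed-loop peak forces land in the 0.05-0.3 N decade
that mice exert through the headpost.

**What the generator does not emulate:** grooming, darting, rapid head
flicks, posture and limb mechanics, tactile-feature interactions, or any
learning dynamics. Passing tests therefore show the *pipelines* are
correct and the *calibration* is self-consistent; they do not certify
behavior of real animals.

## Arenas and task logic

The oval track's controlled path is a rounded rectangle 3 cm inside the
outer wall (straights 27 cm, corner radius 13.5 cm). The 8-maze's goal
arms are circles of 14 cm centerline radius forming an 8 cm channel; the
turning zone is an isosceles triangle (1 cm-scale entry matching the
transition zone, widening to the arm entrances — exact vertices are
configuration, since the construction drawings are not public). Inside
the turning zone, proposed steps are clipped against the triangle by
exact half-plane intersection — the step direction is preserved and only
its magnitude scales — and yaw is clamped to a limit that ramps linearly
from ±20° at the entry to ±45° at 5 cm penetration. The transition zone
ramps lateral and yaw velocities *linearly* to exactly zero over its
3 cm (a cosine ramp is switchable; the hardware spec says only that the
velocities "transition to zero").

In the goal arms the admittance output is tangent to the circle, so it
would integrate off the path; the vector path correction re-terminates
each step radially onto the arc, keeping the radial error at machine
precision indefinitely. The lateral/yaw trajectory servo forms its yaw
error from heading *vectors* (equivalently, rotating by the global arm
angle first), so it is continuous across the ±pi wrap — the suite checks
two representations of the same heading give corrections within 1e-5.

The task engine alternates the cued direction deterministically,
rewards correct choices (8 µL marker), puffs incorrect ones (3 s
marker), emits the cue timelines (left: one 4 s 5 kHz tone; right: four
0.75 s-on/0.25 s-off tones), and voids trials on inconsistent beam
sequences with a warning.

## Behavior analysis

Velocity and acceleration come from finite differences of position,
then a 13-point median filter, then a 5-point mean filter, in that
order; windows shrink at the series edges rather than padding. Only
positive local maxima enter peak statistics (independence of samples),
and `top_fraction_mean` averages the `ceil(f n)` largest. Peak sets are
resampled to n = 100 without replacement (seeded) before
cross-condition comparisons. The admittance plane `F = m a + c v` is fit
by least squares without intercept; with no acceleration variation the
damping-only variant is returned with the mass flagged indeterminate,
and collinear regressors raise an error rather than returning garbage.

Turn scoring measures the maximum contralateral deviation from the
midline through the path's entry point and calls the turn incorrect
strictly above 1 cm; measuring from the entry point makes the score
translation invariant. Tortuosity is the arc-chord ratio (the source
does not define it; this is the field's default). Gait extraction
detects stances where the median-filtered paw speed stays ≤ 0.5 cm/s
for ≥ 3 samples — a literal 0 cm/s never survives tracking noise — and
applies the published exclusions (step < 1 cm or > 10 cm, swing
< 0.05 s). Cadence is the inverse of the same-paw onset-to-onset
interval, again a documented convention. Clopper-Pearson intervals come
from beta quantiles and are tested against an independent binomial-tail
inversion at 1e-10.

## Neural encoding

**Imaging.** ΔF/F = band-passed (4th-order Butterworth, 0.05-5 Hz, zero
phase) `F_cell - 0.7 F_neu`, divided by the mean of the *raw* corrected
trace. The raw-mean denominator resolves an ambiguity: the band-pass
removes DC, so a literal "filtered mean" would be near zero and the
ratio degenerate; the filtered-mean variant remains switchable. Traces
are centered before filtering so zero-phase edge transients stay small.
Cells with non-positive denominators are flagged invalid, not silently
kept. The five inclusion criteria (3 sd < max; sd < 50%; max in
[20%, 500%]; soma in [20, 400] px; aspect in [0.7, 1.4]) treat "between"
as inclusive.

**Electrophysiology.** The mean of the in-brain channels is subtracted
from all channels; voltages are high-passed at 250 Hz; spike counts are
summed in 50 ms windows advanced by 20 ms (exactly 50 S/s), smoothed
with a 260 ms-wide, 20 ms-sd Gaussian (13 taps at one-sample sd), and
z-scored per cell, with flat cells flagged and kept as zeros.

**Predictors and kernels.** The maze is linearized as turning zone →
left arm → right arm. The first ~6 cm of each arm circle lie *inside*
the turning-zone triangle (the zone is the arms' overlap), so the
canonical path skips that stretch — otherwise those bins could never be
visited and the location block could not reach full rank. Location bins
are half-open arc-length intervals (2 cm → 87 bins on the default
geometry; the published 82- and 196-bin variants are reference
configurations reflecting slightly different path coverage, selectable
via `n_bins`). Point events are diagonalized into causal lag columns
(default 0-1 s at the activity rate); continuous covariates are
z-scored. `kernel_pinv` solves `Y = X K` by Moore-Penrose pseudoinverse
(minimum-norm under rank deficiency) after zeroing stationary-sample
rows; predictor columns with fewer than 5 nonzero samples have their
kernel rows zeroed ("fewer than 5 instances" is interpreted as samples;
counting distinct visits instead is a one-line change). `kernel_rrr`
projects the OLS solution onto the leading right singular vectors of the
fitted activity, so full rank reproduces OLS exactly and the residual is
non-increasing in rank; `select_rank_cv` picks a rank by contiguous-fold
cross-validation since the published analyses do not state one.
`normalize_sort` scales each cell by its largest-magnitude weight (the
maximum becomes exactly 1) and orders cells by the location of that
maximum (stable; all-zero cells last) or by depth.

**Synthetic sessions.** `synth_neural_session` drives Gaussian place
cells (centers uniform on the path, 5 cm width, 2-10 Hz peaks) with a
behavior log, spikes them as Poisson, and for imaging convolves with a
0.4 s exponential calcium kernel plus white noise and a shared neuropil
that the 0.7 coefficient exactly cancels. Ground truth is returned for
recovery experiments. "Zero-noise" recovery feeds the expected rates
(Poisson spiking is itself noise); the suite requires ≥ 95% of cells
recovered within one bin there, graceful degradation across three
rate-noise levels, and a diagonally dominant sorted kernel from the
fully composed imaging pipeline. The generator does not emulate
drifting baselines, motion artifacts, overlapping somata, or non-place
coding — recovery results certify the estimators, not real recordings.

## Problem sizes and runtime

The suite's problem sizes are chosen to exercise every estimator at
meaningful statistical power while keeping a full run near ninety
seconds on one core: 1000-sample kinematic round trips, 100-configuration
Jacobian checks, 2 s dynamic trajectories at 1 ms steps, 4 x 300 s
calibration sessions in the module tests and the full 10 x 600 s
condition in the acceptance suite, and 6-10 lap neural sessions with
30-60 cells. The acceptance script's workspace sweep evaluates the full
0.5° grid (~20 M triples, ~25 s vectorized).

## Known limitations

* The dynamic model is a lumped surrogate: no link rotary inertia about
  their own axes (except the payload yaw term), no structural
  compliance, no friction, no motor electrical dynamics.
* The goniometer axis nesting and the turning-zone vertices are
  documented assumptions where the mechanical drawings are not public.
* The loop model aggregates all delays into one pure delay plus one lag;
  it reproduces scaling behavior, not the full multi-state structural
  resonances of the physical machine.
* The virtual mouse is a statistical generator, not a biomechanical
  model; closed-loop results describe the controller, not animal
  behavior.
* Real-cohort statistics (gait means across animals, decision success
  rates, cell counts) are outside the twin's reach by construction and
  are not asserted anywhere.
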