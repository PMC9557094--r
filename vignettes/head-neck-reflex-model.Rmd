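---
title: "A reduced-order head-neck model with reflexive muscle control for rear-impact analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order head-neck model with reflexive muscle control for rear-impact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexneck)
```

## Scope and motivation

Whiplash-associated disorders arise from the rapid head-torso relative
motion of low-speed rear impacts, in which the cervical spine passes
through a characteristic S-shaped retraction phase before the head
extends rearward. Computational studies of this motion need three
ingredients that are awkward to combine: muscle elements whose passive
damping is strong enough to suppress non-physical oscillation of the
cervical column, a reflex controller that stabilizes head orientation
the way the vestibulocollic reflex (VCR) does, and an objective way of
scoring simulated kinematics against reference (volunteer) kinematics.

`reflexneck` packages all three at reduced order: a sagittal-plane
multibody chain (head, C1-C7) driven at T1, Hill-type line muscles with
a parallel damping element (PDE) and co-contraction (CCo), a delayed
proportional-derivative angular-position feedback (APF) controller, a
CORA-style rating module with hierarchical score aggregation, an
eight-configuration feature-ablation matrix, and bounded parameter
identification. A synthetic-reference generator stands in for volunteer
channels so that the entire evaluation loop runs without any external
data.

The package is *not* a finite-element human body model. Its purpose is
methodological: to expose the interaction of PDE damping, muscle tone,
and reflexive feedback on rear-impact head-neck kinematics, and to
provide a fully reproducible harness for the rating and identification
machinery that full-scale models use.

## The multibody chain

Eight rigid bodies (C7 up to the head) are joined by penalty bushings -
a translational spring-damper pair at each intervertebral joint plus a
rotational spring-damper on the relative sagittal angle. T1 is not a
body: its planar trajectory is prescribed, either directly from channel
data or through the base surrogate described below. The convention is x
forward, z up, rotation ry about y with positive ry = extension
(rearward pitch); the working units are mm, ms, kg, which make forces
come out in kN and give the damping coefficient its conventional unit
kN ms/mm^2.

Penalty joints rather than generalized coordinates were chosen because
they mirror the finite compliance of intervertebral discs and make
prescribed-base coupling trivial; their stiffness is a model parameter,
not a numerical trick, and the integrator resolves the resulting
frequencies comfortably (see *Numerical choices*).

Segment masses, inertias, bushing stiffnesses and muscle geometry are
documented surrogates at anthropometric orders of magnitude (female
head 3.7 kg, male 4.4 kg; 18 mm joint spacing; bushing rotational
stiffness 70 kN mm/rad), not values extracted from any particular
published model, and every one of them is overridable through
`build_model(overrides = ...)`. The female and male builds share
topology exactly and differ only in parameter values.

## Muscles

Each muscle is a line element carrying tensile stress

$$\sigma = a\,\sigma_{max}\,f_L(\lambda)\,f_V(\dot\lambda) +
  \sigma_{passive}(\lambda) + c_{PDE}\,\dot\lambda ,$$

multiplied by PCSA and floored at zero (a muscle cannot push). The
force-length factor is a quadratic bell of half-width 0.5; the
force-velocity factor is the classic Hill hyperbola for shortening
(curvature 0.25) with a slope-matched exponential saturation to an
eccentric plateau of 1.4; the passive term is an exponential toe curve
that vanishes at and below optimal length. The strain rate
$\dot\lambda$ is normalized by the optimal length, so the PDE
coefficient $c_{PDE}$ carries kN ms/mm^2 and typical identified values
lie in 0.01-0.05. No serial elastic element is modelled; that omission
is precisely what makes parallel damping so influential, and the PDE
coefficient is therefore a first-class identified parameter rather than
a fixed constant.

The muscle set comprises two aggregated long elements (posterior
extensor group, 2000 mm^2; anterior flexor group, 1000 mm^2) running
from the head to T1 at 45/32 mm offsets, and a segmental
flexor/extensor pair (300 mm^2 each) spanning every joint at 25 mm
offsets. Optimal lengths equal the reference-posture lengths, so the
settled model starts on the plateau of every curve. Peak isometric
stress is 0.7 MPa. These PCSA values are surrogates chosen to give
physiological group strength (maximal extensor moment of a few tens of
kN mm); they are not measurements.

Activation dynamics are deliberately absent: the routed controller
command is applied directly as activation, matching source models in
which activation-time histories are prescribed. An optional first-order
lag could be added per muscle, but the evaluation machinery in this
package never uses one, and adding unidentifiable states to an
identification study weakens it.

## The reflex controller

The APF controller emulates the VCR's function - maintaining head
orientation in space. At the end of gravity settling (t = 0) the head
angle is captured as the reference $\theta_{ref}$; afterwards the error
$e(t) = \theta_{head}(t) - \theta_{ref}$ (positive = extension) is
buffered, and the command is the delayed PD law

$$u(t) = K_{PA}\,e(t - T_{NDA}) + K_{DA}\,\dot e(t - T_{NDA}),$$

in percent contraction. Queries before controller onset return the
neutral value 0, so $u \equiv 0$ for $t < T_{NDA}$: the delay contract
that the tests assert. The error rate uses the same central-difference
operator as `differentiate()` on the raw buffered error, for
determinism and testability. "%contraction" is read as percent of
maximal activation (division by 100), the only reading consistent with
gains in %contraction/rad acting on an activation in [0, 1].

Routing is reciprocal by default: a positive (extension) command adds
$u/100$ to the flexor activation and subtracts it from the extensor
activation about the co-contraction baseline, preserving mean tone; an
agonist-only mode is provided. Reference parameter sets identified for
full-scale female and male models ship as fixtures
(`reference_optimized_params()`); the male proportional gain sits
exactly on the lower search bound 0.01, which we document but do not
reinterpret - with such a gain the proportional path is effectively
inactive and the male reflex is derivative-dominated.

## Settling and scenarios

Each run spans settling plus event: by default 450 ms total of which
the first 150 ms (negative time) settle the model quasi-statically
under gravity. Gravity ramps linearly over the first 50 ms and joint
damping is raised fivefold during the first two-thirds of the settling
window, then restored well before t = 0, so the event never sees the
auxiliary damping. The settle report records the maximum head-angle
drift over the final 50 ms; drift above 0.5 degrees flags the run
"unsettled" without aborting it. Co-contraction tone (default level
0.02) and the head-mass moment are close to balanced by construction,
which is what lets a 150 ms settle converge.

A scenario carries three feature toggles mirroring the ablation matrix:
`cco` (baseline activation on/off), `pde` (damping coefficient on/off)
and `apf` (controller on/off). The eight combinations enumerate the
configuration matrix exactly, from the passive `PSV` row to
`PSV+CCo+PDE+APF`; `run_config_matrix()` executes all eight on the same
input with no per-configuration re-optimization, deliberately: the
ablation isolates feature contributions only if the shared parameters
stay fixed.

## Objective rating

`cora_score()` combines a corridor method and a cross-correlation
method, weighted 0.5/0.5. Corridors derive from the reference signal
alone: inner and outer half-widths are 5% and 50% of the reference
peak over the evaluation interval; the per-sample score is 1 inside the
inner corridor, 0 outside the outer, linear between, and the channel
score is the sample mean. The correlation method scores shape
(normalized cross-correlation at the best admissible shift, floored at
0), size (ratio of squared-signal integrals after shifting) and phase
(linear in the best shift up to 20% of the interval), sub-weighted
0.5/0.25/0.25. The evaluation interval defaults to 0-300 ms after
impact onset.

The corridor fractions are standard defaults; the sub-weights and the
shift cap are this package's own documented choices - reference rating
software does not publish exact internals, so per-channel scores
against third-party references are not claimed reproducible. What *is*
reproducible, exactly, is the aggregation arithmetic. Three schemes
mirror published evaluation tables: `head_neck` (head group = mean of
HCG-x/z/ry; cervical group = mean of C1-C7 rotations; total = mean of
the two groups), `injury_input` (a 5.8 km/h composite of head
x-acceleration and cervical rotational velocities averaged with the
8.1 and 10.0 km/h head-acceleration scores) and `full_body` (mean of
head x-acceleration, the cervical-velocity group and T1
x-acceleration). Group means are computed at full precision and
rounded half-away-from-zero to 3 decimals only for reporting. Fed the
published per-channel cells (`example_rating_tables()`), these schemes
reproduce every published group and total average to all three printed
decimals, except four cells whose printed values are internally
inconsistent with their own per-channel rows by one unit in the last
digit (the source evidently averaged unrounded internal scores); the
tests pin those four to within 0.001 and all others exactly.

## Synthetic references

`make_reference()` generates volunteer-like channel bundles in two
modes. Truth-run mode simulates the model under known parameters and
adds seeded Gaussian noise, smoothed with a 10 ms moving average and
scaled as a fraction of each channel's peak - emulating measurement
smoothness without inventing inter-subject variability structure. Noise
at 2% of peak sits inside the 5% inner corridor by construction, so
ratings against such references stay near-saturated; the recipe warns
when the amplitude reaches the corridor fraction. Analytic mode
produces parameterized extension-then-rebound waveforms for all ten
rating channels; these are placeholders for interface testing, not
validated kinematics, and are labelled as such.

Sled pulses are haversine by default (100 ms duration), normalized
after sampling so the trapezoidal integral equals the stated delta-v
exactly, with presets at 5.8, 8.1 and 10.0 km/h spanning the usual
low-severity test range (rigid seat, 20 degree seatback, no headrest).
The T1 base surrogate passes the sled velocity through a unit-gain
second-order lag (24 Hz, damping ratio 0.8) - the torso path low-passes
and delays the base input - with small acceleration-proportional
vertical and pitch couplings. A full seat-interaction model is out of
scope.

What passing tests on these references do **not** show: agreement with
real volunteer corridors, inter-subject spread, or 3D (lateral/axial)
effects. They show that the machinery - simulation, rating,
identification, ranking - is self-consistent and deterministic.

## Parameter identification

`calibrate()` searches the box $K_{PA}, K_{DA} \in [0.01, 100]$,
$T_{NDA} \in [3.5, 20]$ ms, $c_{PDE} \in [0.01, 0.05]$ kN ms/mm^2,
maximizing the head-neck total average against the reference. The
default budget is 300 objective evaluations. The search is differential
evolution (population 15, F = 0.7, CR = 0.9) seeded with a Latin
hypercube plus the nominal initial point (6, 5, 20, 0.02), followed by
a bounded Levenberg-Marquardt polish of the per-channel rating
residuals (`1 - score`), started from up to three mutually distant
elites and capped at the remaining budget. Three algorithmic choices
deserve comment. First, mutation is `best1bin` rather than the more
exploratory `rand1bin`: within a 300-evaluation budget the exploratory
variant reliably locates the high plateau of the objective but not its
top. Second, the polish exploits structure rather than fighting it:
the objective surface has a shallow curved valley coupling the
derivative gain, the neural delay and the damping coefficient (a
delayed derivative term can be partially imitated by slightly more
parallel damping at a different delay), with objective differences of
only about 1e-4 along it. Axis-aligned pattern search and simplex
methods stall in this valley - every single-coordinate move loses more
transversally than it gains along the valley - but the truth-run
objective is maximal exactly where every per-channel residual
vanishes, which turns identification into a zero-residual nonlinear
least-squares problem; Gauss-Newton steps linearize the residuals and
traverse the valley in a few iterations from points that direct search
cannot leave. Third, simulation failures score 0 rather than erroring,
so the search survives unstable corners of the box.

Identifiability has physical limits worth stating: with gains bounded
at 100 %contraction per rad (or per rad/ms) and head-angle errors below
a radian at rates below 0.01 rad/ms, the reflex modulates activation by
at most a few percent - the APF contribution to the kinematics is
real but second-order next to the PDE. This is why the recovery
checks target the derivative gain and the damping coefficient, the two
parameters with leverage, and why the neural delay recovered from a
truth run can legitimately land elsewhere in the valley.

## Numerical choices

Integration is fixed-step velocity-Verlet (kick-drift-kick) at
dt = 0.05 ms, with velocity-dependent forces evaluated at the half-step
velocity. The stiffest default mode (translational bushing under a
0.25 kg vertebra) has about 2 rad/ms, giving $\omega\,dt \approx 0.1$ -
comfortably stable, and symplectic, which the energy oracle exploits:
with damping and muscles removed, total mechanical energy recomputed
from the trajectory stays within 0.5% over 100 ms of free vibration.
Halving dt changes rating channels by well under 0.1% RMS. Output is
decimated to 1 ms. Divergence (non-finite state) aborts with the first
bad segment and time named; the calibration objective converts that
into a zero score.

Degenerate inputs are handled explicitly: a reference channel that is
identically zero on the evaluation interval makes the corridor
undefined and raises an error rather than a silent 1 or 0; channels
must be uniformly sampled and finite; rating requires the full
ten-channel set, and the missing names are listed.

Problem sizes used by the shipped tests and the acceptance script: the
standard 450 ms scenario at dt = 0.05 ms (12,000 steps, ~0.15 s per
run), recovery at 300 objective evaluations, and the 8-run
configuration matrix - sizes chosen so the whole evaluation loop stays
interactive on a single core.

## Known limitations

Planar kinematics only; no head-to-seat or headrest contact; line
muscles without 3D containment, wrapping, or serial elasticity; a
single-reference corridor rather than a volunteer ensemble corridor;
surrogate anthropometry. The NIC channel is computed from head/T1
x-accelerations as $0.2\,a_{rel} + v_{rel}^2$, but no injury-risk claim
is attached to its values; tissue-level criteria (canal pressure
gradients) are out of scope.
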