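---
title: "Cerebellar adaptation of split-belt walking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebellar adaptation of split-belt walking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitadapt)
```

## The scientific question

When people walk on a split-belt treadmill (the two belts running at
different speeds, here 2:1), their gait is initially asymmetric: step
length asymmetry, SLA = (l_fast − l_slow)/(l_fast + l_slow), starts
clearly negative and then decays toward (or past) symmetry over minutes.
Individuals with cerebellar damage show the initial asymmetry but not
the adaptation. `gaitadapt` implements a mechanistic account of that
adaptation: a planar reflex-controlled musculoskeletal walker whose only
supraspinal element is a cerebellum-like forward model that adapts a
single spinal parameter per leg — the timing of swing initiation — by
gradient descent on a step-velocity-asymmetry prediction error. All
reflex gains are held constant during walking, so any adaptation that
emerges is attributable to timing alone.

## The cerebellar layer

The cerebellum keeps one internal prediction of the step velocity
asymmetry, SVA = (SV_fast − SV_slow)/(SV_fast + SV_slow), with
SV = l/d (step length over step time, per leg). After every heel strike
it computes the error e = ½ (SVA_pred − SVA)² and applies two
gradient-descent updates:

* prediction: SVA_pred ← SVA_pred − α (SVA_pred − SVA), learning rate α;
* motor command: t_leg ← t_leg − β ∂e/∂SV_leg for both legs, a single
  shared adaptation rate β, where t_leg is that leg's swing-initiation
  threshold and the gradients are the closed forms through the SVA
  definition (`error_gradients()`).

The prediction starts at zero (symmetric tied-belt walking). During
symmetric gait the error is zero and nothing changes; at split-belt
onset the error drives both the prediction and the thresholds until
SVA = SVA_pred — a "new normal" whose location depends on the rates:
α sets the asymmetry level at convergence (small α lets the motor
updates run longer before the prediction catches up, shifting SLA
further), β sets the speed of convergence. This interplay is a package
invariant tested on the surrogate loop (`rate_sweep()`).

Timing choices the formulation leaves open, decided here: updates are
applied synchronously at the heel-strike event after refreshing the
triggering leg's step velocity, and both thresholds are updated at every
heel strike using the latest per-leg observations; the motor update uses
the pre-update prediction. The first gait cycle produces no update (one
completed step per leg is required), matching the exclusion of the first
cycle from analysis. Thresholds are clamped from below at 10 ms to keep
the state machine well-posed; clamps are counted and reported. An SLA
error metric is available as a configuration switch for experimentation,
but SVA is the default and the only metric with closed-form gradients.

## The spinal controller

Each leg is driven by a phase state machine (early stance ES, mid-stance
MS, pre-swing PS, swing SW, landing preparation LP) that activates
phase-dependent reflex laws: positive muscle force feedback (Golgi
tendon organ pathway) on the plantarflexors and vasti during stance,
muscle length feedback (spindle pathway) on tibialis anterior and the
hip flexor, constant feedforward excitations, and trunk
proportional-derivative control distributed to the stance-leg hip
muscles, load-weighted. Feedback signals are delayed by distance-based
tiers: 5 ms (hip/trunk), 10 ms (knee), 20 ms (ankle).

The transition that matters for adaptation is MS→PS. Classic reflex
walkers trigger swing initiation at contralateral heel strike; that
trigger fixes double-support duration and blocks interlimb timing
changes, so here MS→PS fires when the time since the leg's *own* heel
strike reaches the threshold t — the quantity the cerebellum adapts. A
fallback (PS entry once the leg has clearly unloaded late in stance)
prevents deadlock when t is never reached; fallback entries are ordinary
events in the log. The free parameter count is asserted at construction:
62 spinal parameters (31 per leg: gains, offsets, constants, PD
gains/target, three state-machine thresholds) plus the two t values
gives 64; the cerebellar α and β make 66.

## Musculoskeletal model and treadmill

The skeleton is a planar 9-DOF linkage: pelvis-trunk segment (lumbar
joint locked at 8.5° flexion, so head-arms-trunk are lumped) with AP and
vertical translation and tilt, plus hip, knee and ankle pin joints per
leg. Segment masses, lengths and inertias approximate a 75 kg, 1.80 m
adult and are configuration, not claims: the exact inertial values of
the reference planar models are not published in full, so plausible
standard values are shipped and flagged as approximations. Each leg has
seven Hill-type muscle-tendon units (HAM, GLU, IL, VAS, GAS, SOL, TA)
with constant moment arms about the spanned joints — a deliberate
planar simplification; wrapping geometry is out of scope.

Muscle mechanics: first-order activation dynamics (τ_act 10 ms, τ_deact
40 ms, minimum excitation 0.01 to avoid singular dynamics), Gaussian
active force-length, quadratic parallel elastic element, quadratic-toe
tendon (unit force at 4 % strain), and a piecewise hyperbolic
force-velocity curve whose closed-form inverse gives the fiber velocity
from the tendon/fiber force balance each step (elastic-tendon default; a
rigid-tendon variant is not needed by any shipped experiment). The
metabolic model is a muscle-level shortening-heat formulation of the
Minetti-Alexander type (rate = a · F_max · v_max · φ(v/v_max), basal
rate 1.2 W/kg), chosen because it is established, smooth, and needs no
fiber-type partition; it sits behind `metabolic_rate()` so variants can
be swapped. Lengthening is costed at the isometric level.

Foot-belt contact uses two spheres per foot (heel, toe) with a
Hunt-Crossley normal force k δ^n (1 + 1.5 c δ̇) and smooth Coulomb
friction against the velocity of the sphere *relative to the belt
surface*, which moves posteriorly at the configured speed. Belts are
realized as an imposed surface velocity on static geometry — the same
contract as translating boxes without unbounded geometry motion. Left
leg walks on the fast belt (1.0 m/s in the main condition; right 0.5).

Integration is semi-implicit Euler at a fixed step, chosen for strict
determinism (identical configuration and seed give bit-identical
trajectories, which the tests assert). The default step is 0.2 ms
rather than the 0.5 ms that a smooth-dynamics argument alone would
allow: the stance-phase friction stiffness at body-weight normal forces
makes 0.5 ms marginally unstable with the explicit friction model, and
0.2 ms restores a comfortable margin at a few seconds of compute per 80 s
simulation. Heel strike is detected as the heel-sphere normal force
crossing 20 N upward with a 50 ms refractory period; toe-off as the
total foot force falling through 20 N. Early stopping follows the
treadmill task: vertical COM below 85 % of its initial height (fall) or
AP COM drift beyond 10 m.

## Objective function and optimization

The treadmill objective is tiered. Tier 1 scores survival:
J_t = 500000/t_end for runs that end before the desired duration, 0
otherwise, so the optimizer first finds parameters that keep the model
on the treadmill. Once J_t = 0 the composite applies: effort
(w_met · mean metabolic rate + w_act · (1/M)∫Σa³, taken literally over
the whole run), upper-body motion (100 per second with |pelvis tilt
velocity| > 10°/s — the accumulation is not fully specified by the
printed description, so the integral form was chosen for smoothness,
with a one-shot variant as a switch), joint-range penalties (ankle
outside [−60°, 60°] in degrees squared-integrated; knee virtual-ligament
limit torque integrated in N·m·s), and position drift |COMx at the
third reference-leg heel strike minus at the last| (reference leg =
fast/left, switchable). Default weights: w_ub 0.05, w_pos 100, w_met
0.001, w_act 20, w_ankle 0.1, w_knee 0.01.

Parameters are found with a standard (μ/μ_w, λ) CMA-ES (λ = 16, initial
σ = 1) operating in a normalized space (each parameter divided by a
per-parameter scale, since the original implementation's scaling is not
published); box bounds are enforced by clamped evaluation with a
quadratic out-of-box penalty. Termination: generation cap, or best
fitness improving less than 1e-4 over a 500-generation window.
Split-belt solutions are grown by the staged ramp protocol: optimize at
tied belts, then reduce the right belt 0.9→0.5 in 0.1 steps, each stage
warm-started from the previous best (`belt_ramp_protocol()`), with
`manual_readjustment()` available to seed selected gains (plantarflexor
force gains, hip-flexor length reflex) by hand between stages.

## The packaged walker and what it is not

`inst/extdata/walker_params_synthetic.json` holds controller parameters
produced by this package's own reduced optimization protocol (short
simulations, hundreds — not thousands — of generations, one seed, on
one CPU), following the staged recipe: tied-belt optimization, belt
ramp 0.9→0.5 with warm starts, manual readjustment of landing/force
reflex gains toward a human-like asymmetric initial gait (the shipped
`manual_overrides_synthetic.json` applied to
`split_belt_base_synthetic.json` reproduces
`split_belt_initial_guess_synthetic.json`), and a final optimization of
all 66 parameters with the cerebellum active. The `_synthetic` suffix
is deliberate: these are stand-ins constructed here, not the original
study's optimized controllers.

What the packaged walker does and does not demonstrate. It walks the
full 80 s split-belt condition in both configurations, and with the
cerebellum the SVA prediction error closes (−0.114 → −0.035 over ~60
strides, an exponential course with a rate of ~11 strides) through
swing-threshold shifts of 20–40 ms, while the reflex-only run stays
static — the adaptation mechanism works end to end in the full
dynamics. What it does not reproduce: the reduced-budget optimizations
converge to a *near-symmetric* early split-belt gait (SLA ≈ 0 instead
of the published −0.17). Manual readjustments large enough to recreate
a strongly negative early SLA destabilized the 80 s runs under
threshold adaptation at this budget. Consequently the SLA magnitude
contrast (|SLA| late < |SLA| early with the cerebellum) does not hold —
SLA moves by about +0.05 as SVA adapts, which *grows* |SLA| from ≈ 0 —
and the corresponding acceptance test is left failing, documented,
rather than weakened. The symmetric tied-belt walker likewise keeps a
small quasi-periodic limit-cycle wobble (per-stride |SVA| up to
~2.4e-3 against the 1e-3 bound its test asserts), although its
cerebellar thresholds stay put to ~1e-6 s over 50 strides, which is the
substantive tied-belt null. Quantitative replication of the published
SLA endpoints (−0.17 → −0.03 with, flat ≈ −0.15 without the cerebellum)
is expressly out of this package's desk-scale test budget.

## The surrogate stride map

`stride_map()` replaces the full dynamics with per-leg affine responses
l = l0 + k_l·t and d = d0 + k_d·t (optional cross-coupling and Gaussian
observation noise). Defaults emulate early 2:1 split-belt gait: fast
step 0.37 m, slow 0.51 m (SLA ≈ −0.17), step times 0.52/0.62 s, and a
threshold sensitivity of 5 cm per 100 ms — order-of-magnitude choices
made once, as configuration, not fitted claims. The map preserves the
property that matters for the closed loop (step velocity increases with
the leg's own threshold) and deliberately omits everything else:
dynamic stability, stance-swing coupling, kinematic detail. A green
surrogate test therefore establishes the correctness of the adaptation
*algorithm* (fixed point, convergence, rate interplay), not the
behavior of the musculoskeletal model, which has its own tests.

## Analysis pipeline conventions

Step length is the AP distance between the calcaneus centers of mass at
a heel strike; step time the interval from the contralateral heel
strike; a stride pairs a fast step with the following slow step; the
first gait cycle is excluded. When averaging across parallel runs
stride-by-stride, trailing strides covered by fewer than two runs are
dropped. The spatial adaptation component is the center-of-oscillation
difference (slow − fast), each center being the mean of the limb angle
(vertical to pelvis-COM→calcaneus-COM vector) at the leg's heel strike
and toe-off; the temporal component is limb phasing, the lag at the peak
cross-correlation of the two limb-angle trajectories normalized to
stride duration, slow leg as reference. The cross-correlation is
computed on zero-mean unit-variance per-stride signals with *circular*
lags (the published description does not fix the lag convention;
circular lags make the symmetric baseline exactly 0.5 and are
insensitive to where the stride is cut). Gait cycles are resampled to
101 points by linear interpolation; waveform similarity uses the
zero-lag Pearson correlation (flagged undefined for constant signals)
and RMSE in degrees. Exponential adaptation fits y = a − b·e^(−s/c) are
computed by profiling the sum of squares over the rate c (the problem is
linear in a, b at fixed c), with a log-spaced multi-start grid — this
removes the starting-value fragility of generic nonlinear least squares
and recovers noiseless parameters to machine precision. Early/late
adaptation windows: 3 strides for SLA statistics, 5 for peak
activations (after 10 ms smoothing), 20 for kinematics comparisons.

## Known limitations

* Planar dynamics, constant moment arms, two contact spheres per foot:
  adequate for sagittal gait mechanics, silent on frontal-plane balance.
* The packaged walker is coarse (reduced optimization budget); its
  absolute step lengths and kinematic waveforms are rougher than the
  published full-scale solutions.
* The metabolic model is one established choice among several; absolute
  metabolic numbers should not be over-interpreted, only comparisons
  under the same model.
* No after-effect/washout phases and no transition from tied to split
  belts: simulations start inside the split-belt condition with an
  already-asymmetric initial guess, as in the modeled protocol.
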