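---
title: "Methods: the sEMG-driven elbow model, its calibration and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sEMG-driven elbow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoelbow)
```

## Scope and model structure

`myoelbow` simulates the elbow joint as a single revolute joint driven by
one lumped flexor (biceps brachii, two recorded heads) and one lumped
extensor (triceps brachii, two recorded heads). The model assumes that all
flexion torque is attributable to the biceps and all extension torque to
the triceps; deeper synergists (brachialis, brachioradialis, anconeus) are
absorbed into the calibrated sEMG gains. The signal flow is

raw sEMG → preprocessing → activation dynamics → recruitment
nonlinearity → contraction dynamics → joint geometry → equation of
motion → θ~sim~,

with muscle lengths and velocities fed back from the geometry into the
contraction dynamics at every step.

The parameter set splits into 37 fixed quantities — derived once per
subject from eight anthropometric measurements plus literature constants —
and 5 free ones (four channel gains *k*, one triceps length offset)
calibrated per trial. One of the model's source documents counts "36"
fixed parameters in one place and "37 of 42" in another; our own ledger
(the `fixed_params` object) enumerates every quantity we actually hold
fixed, which is what matters operationally, and we do not attempt to
reconcile the two counts.

## Fixed parameters and their provenance

| parameter | value / rule | unit | role |
|---|---|---|---|
| B^bic^ | 0.0472 | m | distal biceps insertion = max moment arm |
| A^bic^ | L~ac,ecl~ / 0.9 | m | proximal biceps attachment |
| L~MTC,0~^bic^ | 1.07 · A^bic^ | m | biceps MTC resting length |
| L~M,0~^bic^ | L~MTC,0~^bic^ / 2.48 | m | biceps optimal muscle length |
| A^tric^ | L~ac,ecl~ / 1.22 (m) or / 1.20 (f) | m | triceps origin distance |
| L~M,0~^tric^ | A^tric^ / (3.5 − 0.46) | m | triceps optimal length |
| Lma^tric^ | 0.87 · L~M,0~^tric^ · 3/(2π) | m | constant pulley radius |
| τ~act~, β | 0.0173 s, 0.35 | | activation dynamics |
| A | −0.25 | | recruitment shape, admissible −3 ≤ A ≤ −0.001 |
| w, c | 0.5, ln 0.05 | | force–length bell width and floor |
| N, K~v~ | 1.4, 5 | | eccentric plateau, Hill curvature (young adults) |
| v~M,max~ | 10 · L~M,0~ | m/s | maximal shortening speed |
| K~p~ | 2.78 | | passive elasticity slope (young adults) |
| m~forearm~, m~hand~ | 1.82 %, 0.7 %/0.55 % of body mass | kg | Bernstein fractions |
| L~cog~ | 0.42 · L~ecm,psu~ | m | forearm centre of gravity |
| d | 5 | N·m·s/rad | joint damping (coarse-search value) |
| f~low~, f~high~, order | 4 Hz, 400 Hz, 4 | | sEMG bandpass |

Notes on individual choices:

* **A^bic^ = L~ac,ecl~/0.9** is applied exactly as the ratio is defined in
  its source, although it makes the attachment distance slightly longer
  than the measured upper arm. We deliberately do not "correct" it: the
  downstream ratios were fitted around this convention.
* The triceps origin ratio is defined through the mean origin distance
  Ā^tric^ = L̄~ac,ecl~ − L̄~ac,ax~/2 (halfway from acromion to the
  axillary fold). From the cited population means this gives 0.2795 m
  (male) and 0.2615 m (female), i.e. the tabulated 0.28 m / 0.26 m. The
  male ratio 1.22 reproduces from the unrounded value; the female 1.20
  only reproduces when Ā^tric^ is first rounded to 0.26 m (the unrounded
  route gives 1.19). `literature_ratios()` exposes both routes.
* Subjects outside the male/female categories of the mass-fraction and
  origin-ratio tables use the mean of the two values.
* Hand-force-derived maxima: F~max~^bic^ = T~max~^flex^ / Lma^bic^(90°)
  and F~max~^tric^ = T~max~^ext^ / Lma^tric^, with
  T~max~ = F~hand,max~ · L~ecm,palm~.

## Numerical and structural choices

**Force–velocity continuation.** The concentric branch is Hill's
hyperbola, written so that shortening (v~M~ < 0) reduces force:
F~v~ = (v~max~ + v~M~)/(v~max~ − K~v~·v~M~), floored at 0 beyond the
maximal shortening speed. For lengthening we use
F~v~ = N + (N−1)(v~M~ − v~max~)/(v~max~ + 7.56·K~v~·v~M~). A common
typeset variant of this branch carries a minus sign in the denominator;
that variant has a pole inside (0, v~max~) and is neither monotone nor
bounded, contradicting the physiological boundary behaviour (continuous
value 1 at v~M~ = 0, plateau N at v~M~ = v~max~) that the model is
defined by. The sign originates in a source convention where v~max~ is
negative. Our form is continuous, strictly increasing, equals 1 at rest
and N at +v~max~, and stays within [0, N] on the physiological range.

**Passive force in strain.** The parallel elasticity is evaluated on the
muscle strain, F~p~ = K~p~·((L~M~ − L~M,0~)/L~M,0~)², not on the absolute
length difference in metres: with K~p~ ≈ 2.78 a squared length in m²
would contribute O(10⁻³) of F~max~ even at extreme stretch, making the
term meaningless. The cited source formulation of K~p~ is strain-based.

**Force–length symmetry.** The cubic exponent in the force–length bell is
taken on the absolute normalised deviation, keeping the bell symmetric —
the defining property (equal 5 % force at ±50 % deviation) only holds in
this reading.

**Bandpass order.** "4th-order Butterworth bandpass" is implemented in
the `butter(4, band)` convention of the original analysis environment: a
4th-order lowpass prototype, hence 8 poles and 4th-order slopes on both
band edges. A 1 Hz motion artifact is then attenuated to below 1 % RMS;
a 4-pole reading would only reach ~6 %.

**Causal filtering.** Filtering is single-pass (causal) because the model
targets online prediction — zero-phase filtering would use future samples.
The filter starts from zero state; the first ~0.5 s are flagged as
transient, and the synthetic generator discards a 1.5 s warm-up lead-in
so that emitted trials are transient-free.

**Clamps.** Excitation is clamped to [0, 1] after rectification (the
activation ODE's input contract), the summed per-head neural activation is
clamped to [0, 1] *before* the recruitment nonlinearity (whose
normalisation assumes a unit-interval input; two strongly active heads
could otherwise exceed it), and u itself is clamped to [0, 1] during
integration. No envelope smoothing is applied beyond the activation ODE —
the ODE is the only smoother between rectification and force generation.

**Integration.** The joint equation of motion
J·dω/dt = T~muscles~ + T~gravity~ − d·ω, with point-mass inertia
J = m~forearm~·L~cog~² + (m~hand~ + m~add~)·L~palm~² (consistent with the
lever arms of the static-torque balance), is integrated by fixed-step
semi-implicit Euler at the sEMG sampling period, so excitations need no
interpolation; sub-stepping is available (`n_sub`) and halving the step
changes a standard trial by far less than 0.1° RMS. The activation ODE is
advanced per head by classical RK4 with the excitation held constant over
the step (τ~act~/Δt ≈ 19, well resolved); an exact-exponential stepping
is available as an alternative since the ODE is linear within a step.
Initial conditions come from the measurement: θ₀ = θ~meas~(0), ω₀ from a
5-sample finite difference.

**Geometry guards.** The angle entering the biceps geometry is clamped
from below at θ~min~ = 0 (no effect in the experimental 0–150° range; the
clamp exists because the auxiliary-angle formula degenerates for
hyperextension). The simulated angle is kept inside [0°, 150°] by a stiff
soft-stop spring (100 N·m/rad beyond the bounds) — numerical plumbing that
prevents non-physical configurations, not part of the biomechanics.
Gravity enters as −g·G·sin(α + θ) with g = 9.81 m/s²; the static-phase
balance used for gain estimation is its θ = 90° special case and carries
the same g (the static-torque expression is dimensionally a mass·length
without it). Inside the forward loop the biceps velocity is the analytic
chain rule dL~MTC~/dθ·ω (the pulley gives the triceps velocity exactly);
the series-level `muscle_velocities()` helper uses central differences,
and both agree to 10⁻³ relative on smooth trajectories.

## Calibration

The static hold at the start of a trial is detected as the leading
interval in which θ stays within 3° of its initial median (no tolerance is
prescribed anywhere; 3° over a 0.5 s reference window separates hold from
movement robustly on both clean and noisy trials). Movement periods are
delimited by upward crossings of the 90° midline, debounced at a quarter
nominal period. The SSE objective is evaluated in radians on the
concatenated first three periods — the ranking of parameter sets is
invariant to the angular unit, and radians keep the residuals on the
scale of the optimiser's default tolerances.

Gain starting values come from the static torque balance
k~est~ = (1/ā~static~)·T~static~/T~max~; the balance identifies the
biceps gains only in the lower posture and the triceps gains only in the
upper posture (the other muscle is unloaded there), the remaining gains
default to 1. Bounds are [0.1, 5]·k~est~ per gain and ±0.05 m for the
offset. Stage one draws 1044 uniform points in the box (one U[0,1]⁵
vector per set, mapped affinely; the count is a configurable default, no
special meaning is attached to it) and keeps the SSE argmin — this escapes
the gravity-driven local minimum at small gains. Stage two runs bounded
trust-region Levenberg–Marquardt least squares (`minpack.lm::nls.lm`, the
R counterpart of a trust-region-reflective `lsqnonlin`) for at most 20
iterations with a 10⁻³ relative step tolerance, with the gain lower bounds
relaxed to 0 so a corrupted channel can be faded out entirely. The
refined point is only accepted if it does not increase the SSE, so the
stage is a descent by construction. All randomness flows from explicit
seeds and the callers' RNG state is restored.

## The synthetic-trial generator

Real recordings of the original experiment are not redistributable with
the package, so validation uses fully synthetic trials that emulate the
experimental paradigm: a 5 s static hold at 90°, then 30 s of cyclic
±45° movement at 0.25 Hz (slow) or 0.5 Hz (fast), in the lower
(α ≈ 0°) or upper (α ≈ 180°) posture with 2 or 4 kg added mass, sampled
at 1111.1 Hz. Default ground-truth gains are (1.2, 0.9, 1.1, 0.8) — a
realistic spread around 1 — and the default SNR is 30 dB.

Activation profiles come from inverse dynamics along the nominal
trajectory (inertia, damping, gravity, passive muscle torques, divided by
the active torque per unit activation at the instantaneous length and
velocity), on top of a constant antagonist co-contraction baseline of
0.08: mild co-contraction is physiological and keeps all four channels
informative, without which the antagonist's gains would be unidentifiable
in a given posture. The profiles are mapped back through the recruitment
nonlinearity and the activation-dynamics steady state to per-head
excitation targets (the per-muscle neural activation is split equally
between the heads), which amplitude-modulate a zero-mean unit-variance
band-limited carrier (20–150 Hz, chosen inside the 4–400 Hz passband so
preprocessing is nearly transparent); broadband Gaussian noise is added at
the requested SNR relative to the signal power, and the raw amplitude
scales as 1/k~true~.

The emitted measured angle is the forward model's own response to this
surrogate sEMG processed with the true gains. Two consequences, stated
plainly:

* The ground truth is exactly representable, so calibration on such a
  trial is an *identifiability* experiment for the five free parameters —
  it says nothing about the model's fidelity to real muscle physiology.
  Passing recovery tests therefore validates the optimisation machinery
  and the internal consistency of the pipeline, not biological accuracy,
  and the package makes no claim to reproduce the original population
  results, which require the original 31-subject recordings.
* The open-loop inverse-dynamics profiles realise a slightly smaller and
  lower movement than commanded (activation lag; clamping of the modulated
  envelope). The generator therefore performs exactly one
  amplitude-and-midline correction pass and re-emits; the achieved range
  then matches 90° ± 45° to within a fraction of a degree.

The ground-truth triceps offset defaults to −40 mm: the offset must leave
the triceps slack enough at high flexion that the prescribed 135° peak is
mechanically reachable against the passive elasticity (with a positive
offset the stretched triceps develops tens of N·m of passive extension
torque near 135°, and no admissible activation can flex the arm there).
The surrogate sEMG of a head with zero activation is identically zero, and
trials are bit-reproducible from their seed, including their CSV form.

## Problem sizes used by the shipped tests

The test suite exercises full-scale trials (35 s at 1111.1 Hz, ≈ 39 000
samples) and full-scale calibrations (1044 random-walk sets plus
refinement). The recovery experiment uses ten seeded noisy trials at
30 dB SNR plus two noise-free trials; on one CPU the whole suite runs in
about two minutes, the recovery experiment accounting for most of it.
Forward dynamics and the activation ODE are implemented in compiled code
(Rcpp), which is what makes ~10⁴ forward simulations per calibration
routine.

## Known limitations

* Single revolute joint; the shoulder enters only through the scalar
  posture angle α. No pronation/supination, no two-joint biceps action at
  the shoulder, no wrist.
* Inelastic tendon (justified far below maximal force); no pennation
  angle; no fatigue; no electrode-shift or crosstalk modelling.
* The damping constant, recruitment shape and Hill constants are
  population values, not per-subject estimates; only the five free
  parameters adapt to a trial.
* Synthetic validation tests identifiability, not physiological fidelity
  (see above). Real-data prediction quality is expected to be
  substantially worse than the near-perfect synthetic recovery, as
  reported for the original experiments (median nMAE ≈ 0.16–0.21,
  QS ≈ 0.25–0.40 across conditions).
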