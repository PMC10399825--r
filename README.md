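# myoelbow

Predicting elbow movement from surface electromyography (sEMG) with a
Hill-type biomechanical model of the human forearm.

For close-to-body robotics — active orthoses, exoskeletons, wearables —
muscle activity can be measured at the skin *before* the limb visibly moves.
`myoelbow` implements a forward musculoskeletal model that turns the raw
sEMG of the four easily accessible heads of *biceps* (short, long) and
*triceps brachii* (long, lateral) into a prediction of the elbow angle
θ(t). The model is designed for fast per-user adaptation: of its 42
internal parameters, 37 are fixed from eight simple anthropometric
measurements (three segment lengths, body mass, sex, two maximum hand
forces) plus literature constants, and only 5 remain free — the four sEMG
gains k and a triceps length offset L<sub>offset</sub> — calibrated per
trial in a two-stage optimisation.

## The model

The signal path, per muscle:

1. **Preprocessing** — each raw channel is amplified by its gain *k*,
   bandpass filtered (Butterworth, 4–400 Hz) and rectified, yielding the
   neural excitation *e*(t) ∈ [0, 1].
2. **Activation dynamics** — a first-order nonlinear lag converts *e* into
   the neural activation *u* (Ca²⁺-mediated excitation–contraction
   coupling):

   du/dt + (1/τ<sub>act</sub>)·(β + (1−β)e)·u = e/τ<sub>act</sub>,
   with τ<sub>act</sub> = 17.3 ms, β = 0.35.

   The two head activations of a muscle are summed and passed through the
   exponential recruitment nonlinearity
   a = (e^(A·u) − 1)/(e^A − 1), A = −0.25.
3. **Contraction dynamics** — Hill-type muscle force
   F<sub>M</sub> = F<sub>max</sub>·(a·F<sub>L</sub>(ΔL<sub>M</sub>)·F<sub>v</sub>(v<sub>M</sub>) + F<sub>p</sub>(ΔL<sub>M</sub>)),
   with a bell-shaped force–length curve (5 % force at ±50 % length
   deviation), Hill's hyperbolic force–velocity drop during shortening with
   an eccentric plateau N = 1.4, and a quadratic passive elasticity
   (K<sub>p</sub> = 2.78) beyond the optimal length.
4. **Geometry** — the biceps spans two attachment points (moment arm
   B·sin φ(θ), MTC length by the law of cosines, inelastic tendon); the
   triceps runs over a constant-radius pulley, its length
   0.54·L<sub>M,0</sub> + Lma·θ + L<sub>offset</sub>.
5. **Equation of motion** — torques from both muscles, gravity
   (posture-dependent via the upper-arm angle α) and viscous joint damping
   (d = 5 N·m·s/rad) drive a point-mass forearm + hand + dumbbell inertia;
   semi-implicit Euler integration at the sEMG rate produces θ<sub>sim</sub>(t).

Calibration estimates starting gains from the static hold at the start of
each trial (torque balance against gravity), bounds them to [0.1, 5]× the
estimate, scans 1044 random parameter sets, and refines the winner with
bounded trust-region least squares (≤ 20 iterations) against θ<sub>meas</sub>
over the first three movement periods. Predictions are scored with the mean
absolute error (MAE), the range-normalised nMAE, and the quality score
QS = 1 − nMAE(θ<sub>sim</sub>)/nMAE(θ<sub>const</sub>), which is 1 for a
perfect prediction and 0 for one no better than holding the mean posture.

Because no public recording of the original experiment is available, the
package ships a synthetic-trial generator (`make_trial()`) that emulates
the experimental paradigm — 5 s static hold, then 30 s of ±45° cyclic
movement about 90° in either posture — with surrogate amplitude-modulated
sEMG whose envelopes encode known ground-truth gains.

## Worked example

```r
library(myoelbow)

subject <- anthropometry(L_ac_ecl = 0.358, L_ecm_psu = 0.27, L_ecm_palm = 0.30,
                         body_mass = 78.7, sex = "male",
                         F_hand_max_flex = 202.6, F_hand_max_ext = 167.0)
fixed <- derive_fixed_parameters(subject)
print(fixed)
#> Fixed musculoskeletal model parameters
#>   biceps : A = 0.3978 m, B = 0.0472 m, L_M0 = 0.1716 m, L_T = 0.2540 m, F_max = 1297 N
#>   triceps: A = 0.2934 m, Lma = 0.0401 m, L_M0 = 0.0965 m, L_T = 0.2413 m, F_max = 1249 N
#>   activation: tau = 17.3 ms, beta = 0.35, A = -0.25
#>   segments: m_forearm = 1.43 kg, m_hand = 0.55 kg, cog = 0.113 m

trial <- make_trial(synthetic_trial_spec(anthro = subject, seed = 7))
print(trial)
#> sEMG trial: 38888 samples at 1111.1 Hz (35.0 s), alpha = 0 deg
#>   theta range 44.7 .. 135.0 deg; condition m_add = 2.0 kg, f = 0.25 Hz

cal <- calibrate_trial(trial, fixed, n_sets = 1044, seed = 1)
print(cal)
#> Two-stage calibration
#>   Free parameters: k = (1.198, 0.902, 1.099, 0.799), L_offset = -40.0 mm
#>   SSE: random walk 44.5385 -> refined 0.0008 rad^2
#>   evaluation span: MAE = 0.000 rad | nMAE = 0.000 | QS = 1.000 (range 1.576 rad)

print(trial$meta$true_free)
#> Free parameters: k = (1.200, 0.900, 1.100, 0.800), L_offset = -40.0 mm
```

The derived fixed parameters show the subject's reconstructed muscle
geometry and maximal forces; the calibration recovers the generator's
hidden gains to better than 1 % and the triceps offset exactly, and the
calibrated simulation reproduces the measured angle course (QS = 1.0).

A command-line interface with the same functionality is installed as
`exec/myoelbow` (`synth`, `calibrate`, `simulate`, `evaluate`, `curves`
subcommands).

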