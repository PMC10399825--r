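# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic subject
#'
#' Anthropometry of an average study participant: 0.358 m upper arm, 78.7 kg
#' body mass and maximum hand forces of 202.6 N (flexion) / 167.0 N
#' (extension); forearm lengths of 0.27 m (to the ulnar styloid) and 0.30 m
#' (to the palm grip point) are typical values for that stature.
#'
#' @return An [anthropometry()] object.
#' @export
default_subject <- function() {
  anthropometry(L_ac_ecl = 0.358, L_ecm_psu = 0.27, L_ecm_palm = 0.30,
                body_mass = 78.7, sex = "male",
                F_hand_max_flex = 202.6, F_hand_max_ext = 167.0)
}

#' Specification of a synthetic trial
#'
#' Defines the subject, condition, ground-truth free parameters and signal
#' properties from which [make_trial()] generates a fully synthetic
#' recording: a 5 s static hold at 90 deg followed by 30 s of sinusoidal
#' movement of +/-45 deg about 90 deg at the condition's target frequency.
#'
#' @param anthro Subject anthropometry; [default_subject()] if omitted.
#' @param cond Experimental condition (default: lower posture, 2 kg, 0.25 Hz).
#' @param true_free Ground-truth free parameters encoded in the generated
#'   sEMG (default gains 1.2, 0.9, 1.1, 0.8 and a -40 mm triceps offset; the
#'   offset must leave the triceps slack enough at high flexion that the
#'   +/-45 deg movement is mechanically reachable against its passive
#'   elasticity).
#' @param duration_static,duration_move Durations (s) of the static hold and
#'   the cyclic movement.
#' @param noise_snr Signal-to-noise ratio (dB) of additive broadband noise on
#'   the raw sEMG; `Inf` for noise-free.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed; the full trial is reproducible from it.
#' @return An object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(anthro = default_subject(),
                                 cond = condition(alpha = 0, m_add = 2,
                                                  target_freq = 0.25),
                                 true_free = free_parameters(1.2, 0.9, 1.1, 0.8,
                                                             -0.04),
                                 duration_static = 5, duration_move = 30,
                                 noise_snr = 30, fs = 10000 / 9, seed = 1L) {
  check_number(duration_static, "duration_static")
  check_number(duration_move, "duration_move")
  if (duration_static <= 0 || duration_move <= 0) {
    abort("durations must be positive", "invalid_argument")
  }
  structure(list(anthro = anthro, cond = cond, true_free = true_free,
                 duration_static = duration_static,
                 duration_move = duration_move, noise_snr = noise_snr,
                 fs = fs, seed = as.integer(seed)),
            class = "synthetic_trial_spec")
}

#' Synthetic muscle activation profiles
#'
#' Builds reciprocal biceps/triceps activation time courses that drive the
#' forearm through the specified movement: a tonic level holding 90 deg
#' against gravity during the static phase, then smooth bursts producing a
#' sinusoid of the requested amplitude. The profiles come from inverse
#' dynamics along the nominal trajectory (inertia + damping + gravity +
#' passive muscle torques, divided by the active torque per unit activation
#' at the current length and velocity), on top of a constant antagonist
#' co-contraction baseline so that all four sEMG channels stay informative.
#'
#' @param spec A [synthetic_trial_spec()].
#' @param fixed Fixed parameters; derived from `spec$anthro` if omitted.
#' @param amplitude Movement amplitude (rad) about the midline.
#' @param center Movement midline (rad); approached from 90 deg along the
#'   amplitude ramp (used by the generator's correction pass).
#' @param cocontraction Antagonist baseline activation.
#' @return List with `time`, `a_bic`, `a_tric` and the nominal
#'   `theta_target` (rad).
#' @export
synth_activation_profiles <- function(spec, fixed = NULL,
                                      amplitude = deg2rad(45),
                                      center = pi / 2,
                                      cocontraction = 0.08) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  if (is.null(fixed)) fixed <- derive_fixed_parameters(spec$anthro)
  fs <- spec$fs
  f <- spec$cond$target_freq
  n_static <- round(spec$duration_static * fs)
  n_move <- round(spec$duration_move * fs)
  tm <- (seq_len(n_static + n_move) - 1L) / fs
  t_s <- n_static / fs

  # nominal trajectory: smooth amplitude ramp over the first half period
  tt <- pmax(tm - t_s, 0)
  ramp <- pmin(tt * 2 * f, 1)
  ramp <- ramp^2 * (3 - 2 * ramp)
  theta <- pi / 2 + ramp * (center - pi / 2 + amplitude * sin(2 * pi * f * tt))
  omega <- central_diff(theta, fs)
  accel <- central_diff(omega, fs)

  # geometry and Hill scalings along the nominal trajectory
  phi <- phi_bic(theta, fixed$A_bic, fixed$B_bic, fixed$theta_min)
  Lma_b <- moment_arm_bic(phi, fixed$B_bic)
  L_MTC <- sqrt(fixed$A_bic^2 + fixed$B_bic^2 +
                  2 * fixed$A_bic * fixed$B_bic * cos(theta))
  L_M_b <- L_MTC - fixed$L_T_bic
  v_b <- -(fixed$A_bic * fixed$B_bic * sin(theta)) / L_MTC * omega
  L_M_t <- muscle_length_tric(theta, fixed$L_M0_tric, fixed$Lma_tric,
                              spec$true_free$L_offset_tric)
  v_t <- fixed$Lma_tric * omega

  FL_b <- force_length(L_M_b - fixed$L_M0_bic, fixed$L_M0_bic, fixed$w, fixed$c)
  Fv_b <- force_velocity(v_b, fixed$v_max_factor * fixed$L_M0_bic,
                         fixed$K_v, fixed$N_ecc)
  Fp_b <- passive_force(L_M_b, fixed$L_M0_bic, fixed$K_p)
  FL_t <- force_length(L_M_t - fixed$L_M0_tric, fixed$L_M0_tric, fixed$w, fixed$c)
  Fv_t <- force_velocity(v_t, fixed$v_max_factor * fixed$L_M0_tric,
                         fixed$K_v, fixed$N_ecc)
  Fp_t <- passive_force(L_M_t, fixed$L_M0_tric, fixed$K_p)

  J <- fixed$m_forearm * fixed$L_forearm_cog^2 +
    (fixed$m_hand + spec$cond$m_add) * fixed$L_palm^2
  T_g <- gravity_torque(theta, spec$cond$alpha, fixed$m_forearm, fixed$m_hand,
                        spec$cond$m_add, fixed$L_forearm_cog, fixed$L_palm,
                        fixed$g)
  T_pass <- fixed$F_max_bic * Fp_b * Lma_b - fixed$F_max_tric * Fp_t * fixed$Lma_tric
  T_req <- J * accel + fixed$d_damp * omega - T_g - T_pass

  gain_b <- fixed$F_max_bic * FL_b * Fv_b * Lma_b
  gain_t <- fixed$F_max_tric * FL_t * Fv_t * fixed$Lma_tric
  T_res <- T_req - cocontraction * (gain_b - gain_t)
  a_bic <- pmin(pmax(cocontraction + pmax(T_res, 0) / gain_b, 0), 1)
  a_tric <- pmin(pmax(cocontraction + pmax(-T_res, 0) / gain_t, 0), 1)
  list(time = tm, a_bic = a_bic, a_tric = a_tric, theta_target = theta)
}

#' Synthetic raw sEMG channel for a target activation
#'
#' Builds an amplitude-modulated surrogate sEMG whose processed envelope
#' reproduces a prescribed activation time course: the activation is mapped
#' back through the recruitment nonlinearity and the steady state of the
#' activation dynamics to a target excitation, which modulates a zero-mean
#' band-limited (20-150 Hz, inside the preprocessing passband) unit-variance
#' carrier. The envelope is scaled by the carrier's mean rectified amplitude
#' so that preprocessing with gain `k_true` followed by the activation
#' dynamics recovers the input. Broadband measurement noise is added at the
#' requested SNR (scaled to the signal power). Draws come from R's RNG; seed
#' via `seed` or by setting the stream in the caller.
#'
#' @param a Target activation series in `[0, 1]`.
#' @param k_true True channel gain (> 0); raw amplitude scales as `1/k_true`.
#' @param fs Sampling rate (Hz).
#' @param noise_snr SNR in dB (`Inf` = no noise).
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @param beta,A_shape Activation-dynamics parameters used for the inversion.
#' @param carrier_band Carrier passband (Hz).
#' @return Raw sEMG series (V), same length as `a`.
#' @export
synth_raw_emg <- function(a, k_true, fs, noise_snr = 30, seed = NULL,
                          beta = 0.35, A_shape = -0.25,
                          carrier_band = c(20, 150)) {
  if (any(a < 0 | a > 1)) abort("activation must lie in [0, 1]", "invalid_argument")
  if (k_true <= 0) abort("k_true must be positive", "invalid_argument")
  gen <- function() {
    n <- length(a)
    u <- a_model_inverse(a, A_shape)
    e_target <- beta * u / (1 - (1 - beta) * u)
    bt <- signal::butter(2, carrier_band * 2 / fs, type = "pass")
    carrier <- as.numeric(signal::filter(bt$b, bt$a, stats::rnorm(n)))
    carrier <- carrier / stats::sd(carrier)
    env <- e_target / mean(abs(carrier))
    sig <- env * carrier / k_true
    if (is.finite(noise_snr)) {
      p_sig <- mean(sig^2)
      sig <- sig + stats::rnorm(n, sd = sqrt(p_sig * 10^(-noise_snr / 10)))
    }
    sig
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Generate a complete synthetic trial
#'
#' Runs the full generative pipeline: activation profiles ->
#' per-head surrogate sEMG (the per-muscle neural activation is split
#' equally between the two heads) -> preprocessing with the true gains ->
#' activation dynamics -> forward dynamics. The simulated elbow angle is the
#' trial's measured angle, so the ground-truth free parameters reproduce the
#' trajectory exactly up to the sEMG noise; a recovery experiment on such a
#' trial probes the identifiability of the five free parameters. Because the
#' open-loop inverse-dynamics profiles slightly undershoot the target range,
#' the generator performs one amplitude-correction pass. A lead-in of
#' `lead_in` seconds is generated before the static phase and discarded, so
#' that the bandpass-filter and activation start-up transients (which would
#' otherwise let the arm sag at the very start) are not part of the emitted
#' trial.
#'
#' @param spec A [synthetic_trial_spec()].
#' @param lead_in Discarded warm-up duration (s).
#' @return An [emg_trial()] whose `meta` records `synthetic = TRUE`, the
#'   seed and the ground-truth free parameters (`meta$true_free`).
#' @export
make_trial <- function(spec, lead_in = 1.5) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  fixed <- derive_fixed_parameters(spec$anthro)
  filt <- bandpass_design(spec$fs, fixed$f_low, fixed$f_high, fixed$filter_order)
  ks <- c(spec$true_free$k_bic_short, spec$true_free$k_bic_long,
          spec$true_free$k_tric_long, spec$true_free$k_tric_lat)
  ext <- spec
  ext$duration_static <- spec$duration_static + lead_in
  n_lead <- round(lead_in * spec$fs)

  build <- function(amplitude, center = pi / 2) {
    prof <- synth_activation_profiles(ext, fixed, amplitude = amplitude,
                                      center = center)
    u_b <- a_model_inverse(prof$a_bic, fixed$A_shape)
    u_t <- a_model_inverse(prof$a_tric, fixed$A_shape)
    a_heads <- cbind(a_model(u_b / 2, fixed$A_shape),
                     a_model(u_b / 2, fixed$A_shape),
                     a_model(u_t / 2, fixed$A_shape),
                     a_model(u_t / 2, fixed$A_shape))
    raw <- with_local_seed(spec$seed, {
      vapply(1:4, function(j) {
        synth_raw_emg(a_heads[, j], ks[j], spec$fs, spec$noise_snr,
                      beta = fixed$beta, A_shape = fixed$A_shape)
      }, numeric(length(prof$time)))
    })
    base <- vapply(1:4, function(j) {
      as.numeric(preprocess_emg(raw[, j], k = 1, filt = filt, clamp = FALSE))
    }, numeric(nrow(raw)))
    sim <- forward_simulate(base, spec$fs, fixed, spec$true_free, spec$cond,
                            theta0 = pi / 2, omega0 = 0)
    keep <- (n_lead + 1L):length(prof$time)
    list(time = (seq_along(keep) - 1L) / spec$fs, raw = raw[keep, ],
         theta = sim$theta[keep], theta_target = prof$theta_target[keep])
  }

  # one correction pass: the open-loop profiles realise a slightly smaller
  # and lower movement than commanded (activation lag, envelope clamping)
  target_amp <- deg2rad(45)
  first <- build(target_amp)
  move <- first$time > spec$duration_static + 1 / spec$cond$target_freq
  amp_achieved <- (max(first$theta[move]) - min(first$theta[move])) / 2
  ctr_achieved <- (max(first$theta[move]) + min(first$theta[move])) / 2
  corr <- min(max(target_amp / amp_achieved, 0.5), 2)
  res <- if (abs(corr - 1) > 0.02 || abs(ctr_achieved - pi / 2) > 0.02) {
    build(target_amp * corr, center = pi - ctr_achieved)
  } else first

  emg_trial(res$time, res$raw, res$theta, spec$cond$alpha, spec$cond,
            meta = list(synthetic = TRUE, seed = spec$seed,
                        noise_snr = spec$noise_snr,
                        true_free = spec$true_free,
                        theta_target = res$theta_target))
}
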