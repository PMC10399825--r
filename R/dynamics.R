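#' Net muscular elbow torque
#'
#' Muscle forces act through their moment arms; the biceps flexes (positive
#' torque), the triceps extends (negative):
#' `T = F_bic * Lma_bic - F_tric * Lma_tric`.
#'
#' @param F_bic,F_tric Muscle forces (N), >= 0; vectorised.
#' @param Lma_bic,Lma_tric Moment arms (m).
#' @return Net torque (N m), positive in flexion direction.
#' @export
joint_torque <- function(F_bic, F_tric, Lma_bic, Lma_tric) {
  if (any(F_bic < 0) || any(F_tric < 0)) {
    abort("muscle forces must be non-negative", "invalid_argument")
  }
  F_bic * Lma_bic - F_tric * Lma_tric
}

#' Gravitational elbow torque
#'
#' With the forearm hanging at angle `alpha + theta` from the downward
#' vertical (`alpha` = upper-arm posture, `theta` = elbow flexion), gravity
#' acts on the forearm mass at its centre of gravity and on the hand plus
#' added mass at the palm:
#' `T_g = -g (m_forearm L_cog + (m_hand + m_add) L_palm) sin(alpha + theta)`.
#' At `theta = 90` deg this reduces to the static-phase factor
#' `-g G cos(alpha)`.
#'
#' @param theta Elbow angle (rad); vectorised.
#' @param alpha Upper-arm posture angle (rad).
#' @param m_forearm,m_hand,m_add Masses (kg), >= 0.
#' @param L_cog Forearm centre-of-gravity distance from the elbow (m).
#' @param L_palm Palm distance from the elbow (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return Gravitational torque (N m), negative when gravity extends.
#' @export
gravity_torque <- function(theta, alpha, m_forearm, m_hand, m_add,
                           L_cog, L_palm, g = GRAVITY) {
  if (m_forearm < 0 || m_hand < 0 || m_add < 0) {
    abort("masses must be non-negative", "invalid_argument")
  }
  -g * (m_forearm * L_cog + (m_hand + m_add) * L_palm) * sin(alpha + theta)
}

#' Forward-simulate the elbow from excitation series
#'
#' Integrates the full model: per-head activation dynamics and recruitment
#' nonlinearity, Hill-type contraction dynamics for biceps and triceps,
#' angle-dependent geometry, and the joint equation of motion
#' `J domega/dt = T_muscles + T_gravity - d omega` with point-mass inertia
#' `J = m_forearm L_cog^2 + (m_hand + m_add) L_palm^2`. The integrator is
#' fixed-step semi-implicit Euler at the excitation sampling rate (optionally
#' subdivided via `n_sub`); the simulation range is kept inside
#' `[0, 150]` deg by a soft-stop spring torque at the bounds.
#'
#' @param excitations Numeric matrix with one column per muscle head in the
#'   order biceps short, biceps long, triceps long, triceps lateral. By
#'   default these are unit-gain rectified envelopes and the gains in `free`
#'   are applied (then clamped to `[0, 1]`); set `gains_applied = TRUE` if
#'   the columns are already final excitations.
#' @param fs Sampling rate (Hz).
#' @param fixed A `fixed_params` object from [derive_fixed_parameters()].
#' @param free A `free_params` object (sEMG gains and triceps length offset).
#' @param cond A [condition()] object (posture, added mass).
#' @param theta0 Initial elbow angle (rad).
#' @param omega0 Initial angular velocity (rad/s).
#' @param gains_applied Are the excitation columns already gain-scaled?
#' @param n_sub Integrator substeps per sample (default 1).
#' @param method Activation-step scheme, `"rk4"` or `"exact"`.
#' @return An object of class `simulation_result`: list of equal-length
#'   series `theta`, `omega`, activations, and the torque decomposition
#'   (active/passive per muscle, gravity, damping, soft-stop, net), plus
#'   `fs` and `time`.
#' @export
forward_simulate <- function(excitations, fs, fixed, free = free_parameters(),
                             cond = condition(), theta0 = pi / 2, omega0 = 0,
                             gains_applied = FALSE, n_sub = 1L,
                             method = c("rk4", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(fixed, "fixed_params"), inherits(free, "free_params"),
            inherits(cond, "trial_condition"))
  excitations <- as.matrix(excitations)
  if (ncol(excitations) != 4L) {
    abort("excitations must have 4 columns (bic short/long, tric long/lat)",
          "invalid_argument")
  }
  if (any(!is.finite(excitations))) {
    abort("excitations contain non-finite values", "invalid_signal")
  }
  if (!gains_applied) {
    k <- c(free$k_bic_short, free$k_bic_long, free$k_tric_long, free$k_tric_lat)
    excitations <- sweep(excitations, 2L, k, `*`)
  }
  excitations <- pmin(pmax(excitations, 0), 1)

  par <- c(fixed[c("tau_act", "beta", "A_shape", "w", "c", "N_ecc", "K_v",
                   "v_max_factor", "K_p", "A_bic", "B_bic", "L_T_bic",
                   "L_M0_bic", "L_M0_tric", "Lma_tric", "F_max_bic",
                   "F_max_tric", "m_forearm", "m_hand", "L_forearm_cog",
                   "L_palm", "d_damp", "g", "theta_min")],
           list(L_offset_tric = free$L_offset_tric,
                m_add = cond$m_add, alpha = cond$alpha,
                theta_lo = 0, theta_hi = deg2rad(150), K_stop = 100))

  out <- forward_dynamics_cpp(excitations, 1 / fs, par, theta0, omega0,
                              as.integer(n_sub), method == "exact")
  out$fs <- fs
  out$time <- (seq_len(nrow(excitations)) - 1L) / fs
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Elbow simulation: %d samples at %.1f Hz (%.1f s)\n",
              length(x$theta), x$fs, length(x$theta) / x$fs))
  cat(sprintf("  theta range: %.1f .. %.1f deg\n",
              rad2deg(min(x$theta)), rad2deg(max(x$theta))))
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  data.frame(time_s = x$time, theta_sim_deg = rad2deg(x$theta),
             omega_rad_s = x$omega, a_bic = x$a_bic, a_tric = x$a_tric,
             torque_bic_active = x$torque_bic_active,
             torque_tric_active = x$torque_tric_active,
             torque_bic_passive = x$torque_bic_passive,
             torque_tric_passive = x$torque_tric_passive,
             torque_gravity = x$torque_gravity,
             torque_damping = x$torque_damping,
             torque_stop = x$torque_stop,
             torque_net = x$torque_net)
}
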