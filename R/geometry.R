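#' Biceps line-of-action angle
#'
#' Angle between the biceps muscle line and the forearm. With the proximal
#' attachment at distance `A` from the elbow axis on the upper arm and the
#' distal insertion at distance `B` on the forearm,
#' `phi = atan2(A sin(theta'), B + A cos(theta'))` where `theta'` is the elbow
#' angle clamped from below at `theta_min` (0 = fully extended arm).
#'
#' @param theta Elbow angle (rad); vectorised.
#' @param A_bic,B_bic Attachment distances (m).
#' @param theta_min Lower clamp on the angle entering the geometry (rad).
#' @return Angle phi (rad), same length as `theta`.
#' @export
phi_bic <- function(theta, A_bic, B_bic, theta_min = 0) {
  if (A_bic <= 0 || B_bic <= 0) abort("attachment distances must be positive", "geometry")
  th <- pmax(theta, theta_min)
  atan2(A_bic * sin(th), B_bic + A_bic * cos(th))
}

#' Biceps moment arm
#'
#' Perpendicular distance from the elbow axis to the biceps line of action:
#' `Lma = B sin(phi)`, maximal (= B) when the muscle pulls perpendicular to
#' the forearm.
#'
#' @param phi Line-of-action angle (rad), from [phi_bic()].
#' @param B_bic Distal insertion distance (m).
#' @return Moment arm (m) in `[0, B_bic]` for phi in `[0, pi]`.
#' @export
moment_arm_bic <- function(phi, B_bic) {
  if (B_bic <= 0) abort("B_bic must be positive", "geometry")
  B_bic * sin(phi)
}

#' Biceps musculotendon-complex length
#'
#' `L_MTC = (B + A cos(theta)) / cos(phi)`; algebraically identical to the
#' law-of-cosines form `sqrt(A^2 + B^2 + 2AB cos(theta))` away from
#' phi = 90 deg.
#'
#' @param theta Elbow angle (rad).
#' @param phi Line-of-action angle (rad).
#' @param A_bic,B_bic Attachment distances (m).
#' @return MTC length (m).
#' @export
mtc_length_bic <- function(theta, phi, A_bic, B_bic) {
  cp <- cos(phi)
  if (any(abs(cp) < 1e-12)) {
    abort("singular configuration: biceps line perpendicular to forearm (phi = 90 deg)",
          "geometry")
  }
  (B_bic + A_bic * cos(theta)) / cp
}

#' Biceps muscle length under an inelastic tendon
#'
#' Tendon lengthening is neglected (operation far below maximal force), so
#' the muscle length is the MTC length minus the constant tendon length.
#'
#' @param L_MTC Musculotendon-complex length (m).
#' @param L_T_bic Tendon length (m).
#' @return Muscle length (m).
#' @export
muscle_length_bic <- function(L_MTC, L_T_bic) {
  if (any(L_MTC <= L_T_bic)) {
    abort("MTC shorter than tendon: geometry invalid", "geometry")
  }
  L_MTC - L_T_bic
}

#' Triceps muscle length (pulley model)
#'
#' The triceps moment arm is nearly constant over the elbow range, so the
#' muscle is routed over a pulley of radius `Lma_tric`:
#' `L_M = 0.54 L_M0 + Lma_tric * theta + L_offset`, spanning 0.54 L_M0 (full
#' extension) to 1.41 L_M0 over a third of a revolution. `L_offset` absorbs
#' per-trial geometric inaccuracies and is a calibrated free parameter.
#'
#' @param theta Elbow angle (rad); vectorised.
#' @param L_M0_tric Optimal triceps muscle length (m).
#' @param Lma_tric Pulley radius / moment arm (m).
#' @param L_offset Calibrated length offset (m).
#' @return Muscle length (m).
#' @export
muscle_length_tric <- function(theta, L_M0_tric, Lma_tric, L_offset = 0) {
  L <- 0.54 * L_M0_tric + Lma_tric * theta + L_offset
  if (any(L <= 0)) abort("non-positive triceps muscle length", "geometry")
  L
}

#' Muscle contraction velocities along a joint trajectory
#'
#' The triceps runs over a constant-radius pulley, so its velocity is exactly
#' `Lma_tric * omega`. The biceps muscle length is a nonlinear function of
#' the elbow angle; its velocity is obtained by central finite differences of
#' the muscle-length series. Angular velocity is itself a central difference
#' of `theta`.
#'
#' @param theta Elbow angle series (rad), length >= 2.
#' @param fs Sampling rate (Hz).
#' @param fixed A `fixed_params` object.
#' @param L_offset Triceps length offset (m).
#' @return List with `v_M_bic`, `v_M_tric` (m/s; negative = shortening) and
#'   `omega` (rad/s), all the length of `theta`.
#' @export
muscle_velocities <- function(theta, fs, fixed, L_offset = 0) {
  n <- length(theta)
  if (n < 2L) abort("need at least 2 samples", "invalid_argument")
  omega <- central_diff(theta, fs)
  phi <- phi_bic(theta, fixed$A_bic, fixed$B_bic, fixed$theta_min)
  L_M <- muscle_length_bic(mtc_length_bic(theta, phi, fixed$A_bic, fixed$B_bic),
                           fixed$L_T_bic)
  list(v_M_bic = central_diff(L_M, fs),
       v_M_tric = fixed$Lma_tric * omega,
       omega = omega)
}

central_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d
}
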