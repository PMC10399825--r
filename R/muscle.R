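#' Active force-length relation
#'
#' Bell-shaped dependence of active force on the deviation `dL` of the muscle
#' length from its optimum: `F_L = exp(c * |dL / (L_M0 w)|^3)`. With the
#' standard width `w = 0.5` and shape `c = ln 0.05` the force falls to 5 % of
#' maximum at a length deviation of 50 % of the optimal length.
#'
#' @param dL Length deviation `L_M - L_M0` (m); vectorised.
#' @param L_M0 Optimal muscle length (m).
#' @param w Width of the bell (fraction of `L_M0`).
#' @param c Shape factor (< 0), `ln 0.05` by default.
#' @return Dimensionless force scaling in (0, 1].
#' @export
force_length <- function(dL, L_M0, w = 0.5, c = log(0.05)) {
  if (L_M0 <= 0 || w <= 0 || c >= 0) {
    abort("require L_M0 > 0, w > 0, c < 0", "invalid_argument")
  }
  exp(c * abs(dL / (L_M0 * w))^3)
}

#' Force-velocity relation
#'
#' Hill's hyperbolic force drop during active shortening and a saturating
#' force rise during active lengthening (Aubert/Geyer form). The sign
#' convention is `v_M < 0` for shortening (concentric):
#' \describe{
#'   \item{concentric}{`F_v = (v_max + v_M) / (v_max - K_v v_M)`, floored at
#'     0 for `v_M <= -v_max`.}
#'   \item{eccentric}{`F_v = N + (N - 1)(v_M - v_max) / (v_max + 7.56 K_v
#'     v_M)`, continuous at `v_M = 0` with value 1 and reaching the
#'     eccentric plateau `N` at `v_M = +v_max`.}
#' }
#'
#' @param v_M Muscle velocity (m/s), negative = shortening; vectorised.
#' @param v_max Maximum shortening speed (m/s), > 0 (typically `10 L_M0` per
#'   second).
#' @param K_v Curvature factor.
#' @param N_ecc Eccentric force plateau (1.4 for young adults).
#' @return Dimensionless force scaling in `[0, N_ecc]` on `[-v_max, +v_max]`.
#' @export
force_velocity <- function(v_M, v_max, K_v = 5, N_ecc = 1.4) {
  if (v_max <= 0) abort("v_max must be positive", "invalid_argument")
  conc <- pmax(0, (v_max + v_M) / (v_max - K_v * v_M))
  ecc <- N_ecc + (N_ecc - 1) * (v_M - v_max) / (v_max + 7.56 * K_v * v_M)
  ifelse(v_M < 0, conc, ecc)
}

#' Passive elastic muscle force
#'
#' Quadratic parallel elasticity engaged only beyond the optimal length,
#' expressed in muscle strain: `F_p = K_p * ((L_M - L_M0)/L_M0)^2` for
#' `L_M >= L_M0`, else 0.
#'
#' @param L_M Muscle length (m); vectorised.
#' @param L_M0 Optimal muscle length (m).
#' @param K_p Elasticity slope (2.78 for young adults).
#' @return Dimensionless passive force scaling >= 0.
#' @export
passive_force <- function(L_M, L_M0, K_p = 2.78) {
  if (L_M0 <= 0) abort("L_M0 must be positive", "invalid_argument")
  strain <- (L_M - L_M0) / L_M0
  ifelse(L_M >= L_M0, K_p * strain^2, 0)
}

#' Total Hill-type muscle force
#'
#' `F_M = F_max * (a F_L F_v + F_p)`: activation-scaled active force (product
#' of the force-length and force-velocity scalings) plus the passive elastic
#' force, all scaled by the muscle's maximum isometric force.
#'
#' @param a Muscle activation in `[0, 1]`; vectorised.
#' @param L_M Muscle length (m).
#' @param v_M Muscle velocity (m/s), negative = shortening.
#' @param F_max Maximum isometric force (N).
#' @param L_M0 Optimal muscle length (m).
#' @param w,c Force-length parameters, see [force_length()].
#' @param K_v,N_ecc Force-velocity parameters, see [force_velocity()].
#' @param K_p Passive elasticity slope, see [passive_force()].
#' @param v_max_factor Maximum shortening speed in optimal lengths per second.
#' @return Muscle force (N), >= 0.
#' @export
muscle_force <- function(a, L_M, v_M, F_max, L_M0, w = 0.5, c = log(0.05),
                         K_v = 5, N_ecc = 1.4, K_p = 2.78, v_max_factor = 10) {
  if (any(a < 0 | a > 1)) abort("activation must lie in [0, 1]", "invalid_argument")
  if (F_max <= 0) abort("F_max must be positive", "invalid_argument")
  v_max <- v_max_factor * L_M0
  F_L <- force_length(L_M - L_M0, L_M0, w, c)
  F_v <- force_velocity(v_M, v_max, K_v, N_ecc)
  F_p <- passive_force(L_M, L_M0, K_p)
  F_max * (a * F_L * F_v + F_p)
}
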