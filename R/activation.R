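#' Integrate the activation dynamics ODE
#'
#' First-order nonlinear lag converting neural excitation `e(t)` into neural
#' activation `u(t)`, modelling the calcium-mediated excitation-contraction
#' coupling:
#' `du/dt + (1/tau) (beta + (1 - beta) e(t)) u = e(t)/tau`.
#' The rise time constant is `tau`; `beta` slows the decay when excitation is
#' withdrawn (decay constant `tau/beta`). Integration is fixed-step at the
#' sampling rate, treating `e` as constant over each step; the default
#' scheme is classical RK4, with an exact exponential update as alternative
#' (`e` piecewise constant makes the ODE linear within a step). The result is
#' clamped to `[0, 1]`.
#'
#' @param e Excitation series in `[0, 1]`.
#' @param fs Sampling rate (Hz); must satisfy `fs * tau_act >= 2`.
#' @param tau_act Activation time constant (s), 17.3 ms by default.
#' @param beta Decay ratio in (0, 1), 0.35 by default.
#' @param u0 Initial neural activation; defaults to `e[1]` (quasi-steady
#'   start).
#' @param method `"rk4"` or `"exact"`.
#' @return Neural activation series `u`, same length as `e`.
#' @export
integrate_activation <- function(e, fs, tau_act = 0.0173, beta = 0.35,
                                 u0 = e[1], method = c("rk4", "exact")) {
  method <- match.arg(method)
  if (tau_act <= 0 || beta <= 0 || beta >= 1) {
    abort("require tau_act > 0 and 0 < beta < 1", "invalid_argument")
  }
  if (any(!is.finite(e))) abort("excitation contains non-finite values", "invalid_signal")
  if (any(e < 0 | e > 1)) abort("excitation must lie in [0, 1]", "invalid_signal")
  if (fs * tau_act < 2) {
    abort(sprintf("fs * tau_act = %.2f < 2: integration step too large for stability",
                  fs * tau_act), "stability")
  }
  u <- activation_ode_cpp(as.numeric(e), 1 / fs, tau_act, beta,
                          as.numeric(u0), method == "exact")
  pmin(pmax(u, 0), 1)
}

#' Sum the neural activations of two muscle heads
#'
#' The per-head neural activations of one muscle are summed before entering
#' the recruitment nonlinearity. The sum is clamped to `[0, 1]` because the
#' nonlinearity's normalisation assumes a unit-interval input (two strongly
#' active heads could otherwise exceed 1).
#'
#' @param u_head1,u_head2 Neural activation series of equal length.
#' @return Combined neural activation in `[0, 1]`.
#' @export
combine_heads <- function(u_head1, u_head2) {
  if (length(u_head1) != length(u_head2)) {
    abort("head activation series differ in length", "invalid_argument")
  }
  pmin(u_head1 + u_head2, 1)
}

#' Recruitment nonlinearity (A-model)
#'
#' Exponential mapping from neural activation `u` to muscle activation `a`,
#' capturing the nonlinear relation between stimulation frequency and force
#' with a single shape parameter `A` in `[-3, -0.001]`:
#' `a = (exp(A u) - 1) / (exp(A) - 1)`; `a(0) = 0`, `a(1) = 1`, monotone.
#'
#' @param u Neural activation in `[0, 1]`; vectorised.
#' @param A_shape Shape parameter, < 0 (default -0.25).
#' @return Muscle activation `a` in `[0, 1]`.
#' @export
a_model <- function(u, A_shape = -0.25) {
  if (A_shape == 0) abort("A_shape must be nonzero", "invalid_argument")
  if (any(u < -1e-12 | u > 1 + 1e-12)) {
    abort("neural activation must lie in [0, 1]", "invalid_argument")
  }
  u <- pmin(pmax(u, 0), 1)
  expm1(A_shape * u) / expm1(A_shape)
}

#' Inverse of the recruitment nonlinearity
#'
#' @param a Muscle activation in `[0, 1]`.
#' @param A_shape Shape parameter, < 0.
#' @return Neural activation `u` with `a_model(u) = a`.
#' @export
a_model_inverse <- function(a, A_shape = -0.25) {
  if (A_shape == 0) abort("A_shape must be nonzero", "invalid_argument")
  log1p(pmin(pmax(a, 0), 1) * expm1(A_shape)) / A_shape
}
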