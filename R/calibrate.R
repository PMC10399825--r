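#' Segment a trial into static phase and movement periods
#'
#' Each experiment starts with a nearly motionless hold (the static phase,
#' used to estimate gain starting values) followed by cyclic movement about
#' 90 deg. The static phase ends where the angle first leaves a 3 deg band
#' around the initial median; movement periods are delimited by upward
#' crossings of the 90 deg midline, each period being one up-down cycle.
#'
#' @param theta_meas Measured elbow angle series (rad).
#' @param fs Sampling rate (Hz).
#' @param target_freq Nominal movement frequency (Hz), used only for
#'   plausibility filtering of detected periods.
#' @param theta0 Midline angle (rad), 90 deg by default.
#' @param static_tol Half-width of the static band (rad), 3 deg by default.
#' @param n_periods Number of movement periods to return (3 used for
#'   calibration).
#' @return An object of class `trial_segmentation` with `static_span`
#'   (c(first, last) sample) and `period_spans` (list of c(first, last)).
#' @export
segment_trial <- function(theta_meas, fs, target_freq, theta0 = pi / 2,
                          static_tol = deg2rad(3), n_periods = 3L) {
  n <- length(theta_meas)
  ref <- stats::median(theta_meas[seq_len(min(n, max(2L, round(0.5 * fs))))])
  moving <- which(abs(theta_meas - ref) > static_tol)
  if (!length(moving)) {
    abort("no movement detected: cannot segment periods", "segmentation")
  }
  move_start <- moving[1L]
  if (move_start < 2L) {
    abort("no static phase before movement onset", "segmentation")
  }

  # upward midline crossings after movement onset
  idx <- move_start:(n - 1L)
  up <- idx[theta_meas[idx] < theta0 & theta_meas[idx + 1L] >= theta0]
  bounds <- c(move_start, up[up > move_start])
  # debounce: a period cannot be shorter than a quarter nominal period
  min_len <- round(0.25 * fs / target_freq)
  keep <- c(TRUE, diff(bounds) >= min_len)
  bounds <- bounds[keep]
  if (length(bounds) < n_periods + 1L) {
    abort(sprintf("only %d full period(s) found, need %d",
                  max(0L, length(bounds) - 1L), n_periods), "segmentation")
  }
  spans <- lapply(seq_len(n_periods), function(i) c(bounds[i], bounds[i + 1L] - 1L))
  structure(list(static_span = c(1L, move_start - 1L), period_spans = spans,
                 fs = fs, target_freq = target_freq),
            class = "trial_segmentation")
}

#' @export
print.trial_segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: static %.2f s; %d periods of %s s\n",
              diff(x$static_span) / x$fs, length(x$period_spans),
              paste(sprintf("%.2f", vapply(x$period_spans, diff, 0) / x$fs),
                    collapse = "/")))
  invisible(x)
}

# Unit-gain rectified (unclamped) envelopes of the four channels.
base_excitations <- function(trial, fixed, filt = NULL) {
  if (is.null(filt)) {
    filt <- bandpass_design(trial$fs, fixed$f_low, fixed$f_high,
                            fixed$filter_order)
  }
  vapply(1:4, function(j) {
    as.numeric(preprocess_emg(trial$emg[, j], k = 1, filt = filt, clamp = FALSE))
  }, numeric(nrow(trial$emg)))
}

# Per-muscle activation series at given gains.
muscle_activations <- function(base, fs, fixed, k = rep(1, 4)) {
  e <- pmin(pmax(sweep(base, 2L, k, `*`), 0), 1)
  u <- vapply(1:4, function(j) {
    integrate_activation(e[, j], fs, fixed$tau_act, fixed$beta)
  }, numeric(nrow(e)))
  list(a_bic = a_model(combine_heads(u[, 1], u[, 2]), fixed$A_shape),
       a_tric = a_model(combine_heads(u[, 3], u[, 4]), fixed$A_shape))
}

#' Estimate sEMG gain starting values from the static phase
#'
#' During the static hold the muscular torque balances the weight of forearm,
#' hand and dumbbell: `T_static = g cos(alpha) (m_forearm L_cog + m_hand
#' L_palm + m_add L_palm)` (magnitude). At unit gain the mean muscle
#' activation over the static phase is `a_static`, so the gain that would
#' produce the balancing torque is `k_est = (1/a_static) * T_static/T_max`.
#' The gravity load is carried by the biceps in the lower posture and by the
#' triceps in the upper posture, so the estimate exists only for that muscle;
#' the other muscle's gains default to 1.
#'
#' @param trial An [emg_trial()].
#' @param fixed Fixed model parameters.
#' @param cond Condition; defaults to the trial's.
#' @param seg Optional precomputed [segment_trial()] result.
#' @return Named numeric vector of length 4 (`k_bic_short`, `k_bic_long`,
#'   `k_tric_long`, `k_tric_lat`) with attribute `"estimated"` marking which
#'   entries were actually estimated.
#' @export
estimate_static_gains <- function(trial, fixed, cond = trial$cond, seg = NULL) {
  stopifnot(inherits(trial, "emg_trial"), inherits(fixed, "fixed_params"))
  if (is.null(seg)) {
    seg <- segment_trial(trial$theta_meas, trial$fs, cond$target_freq)
  }
  # skip the filter transient at the start of the static phase
  i0 <- min(seg$static_span[2L], max(2L, round(0.75 * trial$fs)))
  idx <- i0:seg$static_span[2L]

  base <- base_excitations(trial, fixed)
  act <- muscle_activations(base, trial$fs, fixed)
  T_static <- fixed$g * abs(cos(cond$alpha)) *
    (fixed$m_forearm * fixed$L_forearm_cog +
       (fixed$m_hand + cond$m_add) * fixed$L_palm)

  k_est <- c(k_bic_short = 1, k_bic_long = 1, k_tric_long = 1, k_tric_lat = 1)
  estimated <- c(FALSE, FALSE, FALSE, FALSE)
  if (cos(cond$alpha) > 0.5) {          # lower posture: biceps loaded
    a_bar <- mean(act$a_bic[idx])
    if (a_bar <= 0) abort("zero biceps activation in static phase", "zero_activation")
    k_est[1:2] <- (1 / a_bar) * T_static / fixed$T_max_flex
    estimated[1:2] <- TRUE
  } else if (cos(cond$alpha) < -0.5) {  # upper posture: triceps loaded
    a_bar <- mean(act$a_tric[idx])
    if (a_bar <= 0) abort("zero triceps activation in static phase", "zero_activation")
    k_est[3:4] <- (1 / a_bar) * T_static / fixed$T_max_ext
    estimated[3:4] <- TRUE
  }
  attr(k_est, "estimated") <- estimated
  k_est
}

#' Optimisation bounds for the five free parameters
#'
#' Gains are constrained to `[0.1, 5]` times their static-phase estimate to
#' enforce realistic values; the triceps length offset to +/-0.05 m.
#'
#' @param k_est Length-4 vector of gain estimates (> 0).
#' @return List with `lower` and `upper`, each length 5 (4 gains + offset).
#' @export
parameter_bounds <- function(k_est) {
  if (any(k_est <= 0)) abort("gain estimates must be positive", "invalid_argument")
  list(lower = c(0.1 * k_est, L_offset = -0.05),
       upper = c(5 * k_est, L_offset = 0.05))
}

#' Build the calibration objective for a trial
#'
#' Precomputes the unit-gain excitation envelopes, the evaluation span (the
#' first three movement periods) and the initial state (initial angle from
#' the measurement, initial velocity from a 5-sample finite difference), and
#' returns residual and sum-of-squared-error functions of the 5-parameter
#' vector `(k1..k4, L_offset)`. Residuals are in radians.
#'
#' @param trial An [emg_trial()].
#' @param fixed Fixed model parameters.
#' @param cond Condition; defaults to the trial's.
#' @param seg Optional precomputed segmentation.
#' @return List with functions `residual(par)` and `sse(par)`, plus the
#'   evaluation index vector `eval_idx` and `seg`.
#' @export
make_objective <- function(trial, fixed, cond = trial$cond, seg = NULL) {
  if (is.null(seg)) {
    seg <- segment_trial(trial$theta_meas, trial$fs, cond$target_freq)
  }
  eval_idx <- unlist(lapply(seg$period_spans, function(s) s[1]:s[2]))
  # nothing after the last evaluated sample influences the SSE
  base <- base_excitations(trial, fixed)[seq_len(max(eval_idx)), , drop = FALSE]
  theta0 <- trial$theta_meas[1L]
  omega0 <- (trial$theta_meas[5L] - trial$theta_meas[1L]) * trial$fs / 4
  theta_ref <- trial$theta_meas[eval_idx]

  residual <- function(par) {
    free <- free_from_vector(par)
    sim <- forward_simulate(base, trial$fs, fixed, free, cond,
                            theta0 = theta0, omega0 = omega0)
    sim$theta[eval_idx] - theta_ref
  }
  list(residual = residual,
       sse = function(par) sum(residual(par)^2),
       eval_idx = eval_idx, seg = seg)
}

#' Global random-walk search over the parameter box
#'
#' Stage one of the calibration: `n_sets` parameter vectors are drawn
#' uniformly in `[0, 1]^5`, mapped affinely onto the bounds, simulated, and
#' the vector with the smallest sum of squared angle errors is returned.
#' The scan guards against the local minimum in which the forearm is driven
#' by gravity alone. Deterministic for a given seed.
#'
#' @param objective Function mapping a length-5 parameter vector to an SSE.
#' @param bounds Bounds from [parameter_bounds()].
#' @param n_sets Number of random parameter sets (default 1044).
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return List with `par` (best vector), `sse`, and the per-set `sse_trace`.
#' @export
random_walk_search <- function(objective, bounds, n_sets = 1044L, seed = NULL) {
  if (n_sets < 1L) abort("n_sets must be >= 1", "invalid_argument")
  draw <- function() matrix(runif(n_sets * 5L), ncol = 5L)
  un <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  par_mat <- sweep(sweep(un, 2L, bounds$upper - bounds$lower, `*`),
                   2L, bounds$lower, `+`)
  sse <- vapply(seq_len(n_sets), function(i) {
    tryCatch(objective(par_mat[i, ]), myoelbow_error = function(e) Inf)
  }, numeric(1L))
  if (all(!is.finite(sse))) {
    abort("all random-walk simulations failed", "search_failure")
  }
  best <- which.min(sse)
  list(par = par_mat[best, ], sse = sse[best], sse_trace = sse)
}

#' Bounded local least-squares refinement
#'
#' Stage two: trust-region (Levenberg-Marquardt) nonlinear least squares on
#' the angle residual, started from the random-walk winner. The gain lower
#' bounds are relaxed to zero in this step so the optimiser can fade out an
#' unreliable sEMG channel; the offset bounds stay at +/-0.05 m. Terminates
#' after at most `max_iter` iterations or when the relative step falls below
#' `step_tol`. The refined point is kept only if it does not increase the
#' SSE.
#'
#' @param start Length-5 start vector (inside the bounds).
#' @param bounds Bounds from [parameter_bounds()].
#' @param residual Function mapping a parameter vector to the residual
#'   vector.
#' @param max_iter Iteration cap (default 20).
#' @param step_tol Minimum relative step (default 1e-3).
#' @return List with `par`, `sse`, `sse_start` and the optimiser `info`.
#' @export
local_refine <- function(start, bounds, residual, max_iter = 20L,
                         step_tol = 1e-3) {
  r0 <- residual(start)
  if (any(!is.finite(r0))) {
    abort("objective not finite at the start point", "search_failure")
  }
  sse0 <- sum(r0^2)
  lower <- c(0, 0, 0, 0, bounds$lower[[5L]])
  upper <- as.numeric(bounds$upper)
  safe_resid <- function(par) {
    tryCatch(residual(par), myoelbow_error = function(e) r0 * 0 + 1e6)
  }
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(start, lower), upper), lower = lower, upper = upper,
    fn = safe_resid,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ptol = step_tol))
  sse1 <- sum(residual(fit$par)^2)
  if (is.finite(sse1) && sse1 <= sse0) {
    list(par = fit$par, sse = sse1, sse_start = sse0, info = fit$info)
  } else {
    list(par = start, sse = sse0, sse_start = sse0, info = fit$info)
  }
}

#' Two-stage calibration of the five free parameters
#'
#' End-to-end per-trial calibration: segment the trial, estimate gain
#' starting values from the static phase, build the bounds, run the
#' random-walk scan and refine the winner by bounded least squares. The SSE
#' is evaluated on the concatenated first three movement periods.
#'
#' @param trial An [emg_trial()].
#' @param fixed Fixed parameters (or an [anthropometry()], from which they
#'   are derived).
#' @param cond Condition; defaults to the trial's.
#' @param n_sets Random-walk sample count (default 1044).
#' @param seed Integer seed for the random walk.
#' @param max_iter,step_tol Refinement termination, see [local_refine()].
#' @return Object of class `calibration`: `free` (the calibrated
#'   [free_parameters()]), `sse`, `sse_random_walk`, `k_est`, `bounds`,
#'   `seg`, `seed`, `n_sets` and the evaluation metrics of the calibrated
#'   simulation over the evaluation span (`metrics`).
#' @export
calibrate_trial <- function(trial, fixed, cond = trial$cond, n_sets = 1044L,
                            seed = 1L, max_iter = 20L, step_tol = 1e-3) {
  if (inherits(fixed, "anthropometry")) fixed <- derive_fixed_parameters(fixed)
  seg <- segment_trial(trial$theta_meas, trial$fs, cond$target_freq)
  k_est <- estimate_static_gains(trial, fixed, cond, seg)
  bounds <- parameter_bounds(k_est)
  obj <- make_objective(trial, fixed, cond, seg)
  rw <- random_walk_search(obj$sse, bounds, n_sets = n_sets, seed = seed)
  ref <- local_refine(rw$par, bounds, obj$residual, max_iter, step_tol)
  free <- free_from_vector(ref$par)
  res <- obj$residual(ref$par)
  theta_ref <- trial$theta_meas[obj$eval_idx]
  m <- evaluate_prediction(theta_ref + res, theta_ref, unit = "rad")
  structure(list(free = free, sse = ref$sse, sse_random_walk = rw$sse,
                 k_est = k_est, bounds = bounds, seg = seg, seed = seed,
                 n_sets = n_sets, metrics = m),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("Two-stage calibration\n  ")
  print(x$free)
  cat(sprintf("  SSE: random walk %.4f -> refined %.4f rad^2\n",
              x$sse_random_walk, x$sse))
  cat("  evaluation span: ")
  print(x$metrics)
  invisible(x)
}

#' Simulate a trial with given free parameters
#'
#' Convenience wrapper: preprocesses the trial's raw sEMG and runs the
#' forward model, initialised from the measured angle.
#'
#' @param trial An [emg_trial()].
#' @param fixed Fixed parameters (or anthropometry).
#' @param free Free parameters.
#' @param cond Condition; defaults to the trial's.
#' @return A `simulation_result`.
#' @export
simulate_trial <- function(trial, fixed, free = free_parameters(),
                           cond = trial$cond) {
  if (inherits(fixed, "anthropometry")) fixed <- derive_fixed_parameters(fixed)
  base <- base_excitations(trial, fixed)
  omega0 <- (trial$theta_meas[5L] - trial$theta_meas[1L]) * trial$fs / 4
  forward_simulate(base, trial$fs, fixed, free, cond,
                   theta0 = trial$theta_meas[1L], omega0 = omega0)
}
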