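#' Mean absolute error between simulated and measured angle
#'
#' `MAE = mean(|theta_sim - theta_meas|)`; independent of recording length.
#'
#' @param theta_sim,theta_meas Equal-length numeric series (any consistent
#'   angular unit).
#' @return MAE in the unit of the inputs.
#' @export
mae <- function(theta_sim, theta_meas) {
  if (length(theta_sim) != length(theta_meas)) {
    abort("series differ in length", "metric")
  }
  if (length(theta_sim) < 1L) abort("empty series", "metric")
  mean(abs(theta_sim - theta_meas))
}

#' Range-normalised mean absolute error
#'
#' `nMAE = MAE / (max(theta_meas) - min(theta_meas))`; amplitude-invariant
#' but still sensitive to the waveform. An nMAE of 0.1 over a 90 deg
#' movement range corresponds to a 9 deg mean deviation.
#'
#' @inheritParams mae
#' @return Dimensionless nMAE >= 0.
#' @export
nmae <- function(theta_sim, theta_meas) {
  rng <- max(theta_meas) - min(theta_meas)
  if (rng <= 0) abort("measured range is zero: nMAE undefined", "metric")
  mae(theta_sim, theta_meas) / rng
}

#' Quality score relative to a constant-mean prediction
#'
#' `QS = 1 - nMAE(theta_sim) / nMAE(theta_const)` with `theta_const` the
#' arithmetic mean of the measurement. QS is 1 for a perfect prediction, 0
#' when the prediction is no better than holding the mean posture, negative
#' for a worse constant offset, and -- unlike nMAE -- independent of the
#' waveform, enabling comparison across movements.
#'
#' @inheritParams mae
#' @return Dimensionless QS <= 1.
#' @export
quality_score <- function(theta_sim, theta_meas) {
  ref <- nmae(rep(mean(theta_meas), length(theta_meas)), theta_meas)
  if (ref <= 0) abort("constant-prediction nMAE is zero: QS undefined", "metric")
  1 - nmae(theta_sim, theta_meas) / ref
}

#' Full evaluation report for a prediction
#'
#' @inheritParams mae
#' @param unit Label recorded with the report (e.g. `"deg"`).
#' @return An object of class `metrics_report` with `mae`, `nmae`, `qs` and
#'   `range_meas`.
#' @export
evaluate_prediction <- function(theta_sim, theta_meas, unit = "rad") {
  structure(list(mae = mae(theta_sim, theta_meas),
                 nmae = nmae(theta_sim, theta_meas),
                 qs = quality_score(theta_sim, theta_meas),
                 range_meas = max(theta_meas) - min(theta_meas),
                 unit = unit),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MAE = %.3f %s | nMAE = %.3f | QS = %.3f (range %.3f %s)\n",
              x$mae, x$unit, x$nmae, x$qs, x$range_meas, x$unit))
  invisible(x)
}
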