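TRIAL_COLUMNS <- c("time_s", "emg_bic_short_V", "emg_bic_long_V",
                   "emg_tric_long_V", "emg_tric_lat_V", "theta_deg",
                   "alpha_deg")

#' Construct a trial object
#'
#' A trial bundles the time-aligned raw recordings of one experiment: the
#' four raw sEMG channels, the measured elbow angle, the (scalar) upper-arm
#' posture angle and the experimental condition. Angles are radians
#' internally; the CSV interface uses degrees.
#'
#' @param time Uniform time base (s).
#' @param emg Numeric matrix, columns `bic_short`, `bic_long`, `tric_long`,
#'   `tric_lat` (V).
#' @param theta_meas Measured elbow angle series (rad).
#' @param alpha Upper-arm posture angle (rad, scalar).
#' @param cond A [condition()] object.
#' @param meta Free-form provenance list.
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(time, emg, theta_meas, alpha, cond = NULL,
                      meta = list()) {
  emg <- as.matrix(emg)
  n <- length(time)
  if (nrow(emg) != n || length(theta_meas) != n) {
    abort("time, emg and theta_meas must have equal length", "schema")
  }
  if (ncol(emg) != 4L) abort("emg must have 4 columns", "schema")
  if (n >= 2L) {
    dt <- diff(time)
    if (any(dt <= 0)) abort("time base must be strictly increasing", "schema")
  }
  colnames(emg) <- c("bic_short", "bic_long", "tric_long", "tric_lat")
  if (is.null(cond)) cond <- condition(alpha = alpha)
  fs <- if (n >= 2L) 1 / mean(diff(time)) else NA_real_
  structure(list(time = time, emg = emg, theta_meas = theta_meas,
                 alpha = alpha, cond = cond, fs = fs, meta = meta),
            class = "emg_trial")
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("sEMG trial: %d samples at %.1f Hz (%.1f s), alpha = %.0f deg\n",
              length(x$time), x$fs, length(x$time) / x$fs, rad2deg(x$alpha)))
  cat(sprintf("  theta range %.1f .. %.1f deg; condition m_add = %.1f kg, f = %.2f Hz\n",
              rad2deg(min(x$theta_meas)), rad2deg(max(x$theta_meas)),
              x$cond$m_add, x$cond$target_freq))
  invisible(x)
}

#' Read a trial from CSV
#'
#' The CSV must carry exactly the columns `time_s`, `emg_bic_short_V`,
#' `emg_bic_long_V`, `emg_tric_long_V`, `emg_tric_lat_V`, `theta_deg`,
#' `alpha_deg`. Angles are converted to radians. A non-uniform time base is
#' resampled onto a uniform grid by linear interpolation with a warning
#' (recorded in `meta$resampled`).
#'
#' @param path CSV file path.
#' @param cond Optional [condition()]; defaults to one built from the file's
#'   `alpha_deg`.
#' @return An [emg_trial()] object.
#' @export
read_trial <- function(path, cond = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path), "io")
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing)) {
    abort(paste("trial CSV is missing column(s):", paste(missing, collapse = ", ")),
          "schema")
  }
  tm <- df$time_s
  if (any(diff(tm) <= 0)) abort("time base must be strictly increasing", "schema")
  meta <- list(resampled = FALSE)
  dt <- diff(tm)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
    warning("non-uniform time base: resampling onto a uniform grid")
    grid <- seq(tm[1], tm[length(tm)], length.out = length(tm))
    for (colm in setdiff(TRIAL_COLUMNS, "time_s")) {
      df[[colm]] <- stats::approx(tm, df[[colm]], xout = grid)$y
    }
    df$time_s <- grid
    meta$resampled <- TRUE
  }
  alpha <- deg2rad(df$alpha_deg[1])
  if (is.null(cond)) cond <- condition(alpha = alpha)
  emg_trial(df$time_s,
            as.matrix(df[, c("emg_bic_short_V", "emg_bic_long_V",
                             "emg_tric_long_V", "emg_tric_lat_V")]),
            deg2rad(df$theta_deg), alpha, cond, meta)
}

#' Write a trial to CSV
#'
#' Inverse of [read_trial()]; angles are written in degrees. Values are
#' formatted with enough digits that a write/read round trip preserves them
#' to better than 1e-9.
#'
#' @param trial An [emg_trial()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "emg_trial"))
  df <- data.frame(time_s = trial$time,
                   emg_bic_short_V = trial$emg[, 1],
                   emg_bic_long_V = trial$emg[, 2],
                   emg_tric_long_V = trial$emg[, 3],
                   emg_tric_lat_V = trial$emg[, 4],
                   theta_deg = rad2deg(trial$theta_meas),
                   alpha_deg = rad2deg(trial$alpha))
  txt <- vapply(df, function(col) sprintf("%.12g", col), character(nrow(df)))
  lines <- c(paste(TRIAL_COLUMNS, collapse = ","),
             apply(matrix(txt, nrow = nrow(df)), 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject/condition configuration file
#'
#' YAML or JSON (by extension) with keys `anthropometry.{L_ac_ecl_m,
#' L_ecm_psu_m, L_ecm_palm_m, body_mass_kg, sex, F_hand_max_flex_N,
#' F_hand_max_ext_N}` and `condition.{alpha_deg, m_add_kg, target_freq_hz}`.
#'
#' @param path Config file path (`.yaml`, `.yml` or `.json`).
#' @return List with elements `anthro` ([anthropometry()]) and `cond`
#'   ([condition()]).
#' @export
read_subject_config <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path), "io")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  a <- cfg$anthropometry
  need <- c("L_ac_ecl_m", "L_ecm_psu_m", "L_ecm_palm_m", "body_mass_kg",
            "sex", "F_hand_max_flex_N", "F_hand_max_ext_N")
  missing <- setdiff(need, names(a))
  if (length(missing)) {
    abort(paste("config missing anthropometry key(s):",
                paste(missing, collapse = ", ")), "schema")
  }
  anthro <- anthropometry(a$L_ac_ecl_m, a$L_ecm_psu_m, a$L_ecm_palm_m,
                          a$body_mass_kg, a$sex, a$F_hand_max_flex_N,
                          a$F_hand_max_ext_N)
  cc <- cfg$condition
  cond <- condition(alpha = deg2rad(cc$alpha_deg %||% 0),
                    m_add = cc$m_add_kg %||% 2,
                    target_freq = cc$target_freq_hz %||% 0.25)
  list(anthro = anthro, cond = cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
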