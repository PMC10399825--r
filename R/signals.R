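#' Design the sEMG bandpass filter
#'
#' Butterworth bandpass with the standard sEMG corner frequencies of 4 and
#' 400 Hz. `order` is the order of the Butterworth lowpass prototype (the
#' usual `butter(n, band)` convention), so the default 4th-order design has
#' 8 poles and rolls off with 4th-order slopes on both band edges.
#'
#' @param fs Sampling rate (Hz).
#' @param f_low,f_high Corner frequencies (Hz), `0 < f_low < f_high < fs/2`.
#' @param order Prototype filter order.
#' @return An object of class `bandpass_filter`: list with transfer-function
#'   coefficients `b`, `a` and the design parameters.
#' @export
bandpass_design <- function(fs, f_low = 4, f_high = 400, order = 4) {
  check_number(fs, "fs")
  check_number(order, "order", lower = 1)
  if (f_low <= 0 || f_high <= f_low) {
    abort("require 0 < f_low < f_high", "invalid_argument")
  }
  if (f_high >= fs / 2) {
    abort(sprintf("f_high = %g Hz must be below the Nyquist frequency %g Hz",
                  f_high, fs / 2), "nyquist")
  }
  bt <- signal::butter(order, c(f_low, f_high) * 2 / fs, type = "pass")
  structure(list(b = bt$b, a = bt$a, fs = fs, f_low = f_low, f_high = f_high,
                 order = order),
            class = "bandpass_filter")
}

#' @export
print.bandpass_filter <- function(x, ...) {
  cat(sprintf("Butterworth bandpass: order %d, %g-%g Hz at fs = %g Hz (%s)\n",
              x$order, x$f_low, x$f_high, x$fs,
              if (filter_stable(x)) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Check stability of a designed filter
#'
#' @param filt A `bandpass_filter` object.
#' @return `TRUE` if all poles lie strictly inside the unit circle.
#' @export
filter_stable <- function(filt) {
  all(Mod(polyroot(rev(filt$a))) < 1)
}

#' Preprocess a raw sEMG channel into neural excitation
#'
#' The raw signal is amplified by the gain `k`, bandpass filtered (causally,
#' single pass: the model targets online prediction, so zero-phase filtering
#' is not available) and full-wave rectified; the result is clamped to
#' `[0, 1]` to satisfy the input contract of the activation dynamics:
#' `e = clamp(|bandpass(k * raw)|, 0, 1)`.
#'
#' The filter state is initialised to zero, so the first ~0.5 s contain the
#' filter transient (`attr(e, "transient_s")`).
#'
#' @param raw Raw sEMG samples (V).
#' @param k Amplification gain, >= 0.
#' @param filt A [bandpass_design()] filter. If `NULL`, a default 4th-order
#'   4-400 Hz filter at `fs` is designed.
#' @param fs Sampling rate (Hz); required when `filt` is `NULL`.
#' @param clamp If `FALSE`, the rectified signal is returned without the
#'   upper clamp (used internally where the gain is applied later).
#' @return Numeric excitation series `e` in `[0, 1]`, same length as `raw`,
#'   with attributes `fs` and `transient_s`.
#' @export
preprocess_emg <- function(raw, k = 1, filt = NULL, fs = NULL, clamp = TRUE) {
  if (any(!is.finite(raw))) abort("raw sEMG contains non-finite samples", "invalid_signal")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    abort("gain k must be a single number >= 0", "invalid_argument")
  }
  if (is.null(filt)) {
    if (is.null(fs)) abort("supply `filt` or `fs`", "invalid_argument")
    filt <- bandpass_design(fs)
  }
  e <- abs(as.numeric(signal::filter(filt$b, filt$a, k * raw)))
  if (clamp) e <- pmin(e, 1)
  attr(e, "fs") <- filt$fs
  attr(e, "transient_s") <- 0.5
  e
}
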