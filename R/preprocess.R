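#' Low-pass filter specification
#'
#' Maximally-flat (Butterworth) IIR low-pass used to suppress surface-scanner
#' noise while preserving the breathing band (typically 0.1-0.5 Hz). The
#' defaults -- order 8, 1 Hz cutoff -- attenuate a 5 Hz component by more than
#' five orders of magnitude while leaving a 0.25 Hz breathing harmonic
#' untouched.
#'
#' @param order Filter order (numerator and denominator), >= 1.
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist rate of
#'   the signal it is applied to.
#' @param mode `"zero_phase"` applies the filter forward and backward (no
#'   phase lag; used offline and on finite windows); `"causal"` filters
#'   forward only, for strictly streaming use.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 8, cutoff_hz = 1.0,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (order < 1 || order != round(order)) {
    bc_abort("bc_invalid_filter", "order must be a positive integer.")
  }
  if (cutoff_hz <= 0) {
    bc_abort("bc_invalid_filter", "cutoff_hz must be positive.")
  }
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz, mode = mode),
            class = "bc_filter_spec")
}

# Butterworth coefficients, DC gain renormalised to exactly 1.
butter_coefs <- function(spec, rate_hz) {
  if (spec$cutoff_hz >= rate_hz / 2) {
    bc_abort("bc_invalid_filter",
             sprintf("cutoff %.3g Hz is at or above Nyquist (%.3g Hz).",
                     spec$cutoff_hz, rate_hz / 2))
  }
  bf <- signal::butter(spec$order, 2 * spec$cutoff_hz / rate_hz, type = "low")
  b <- bf$b * (sum(bf$a) / sum(bf$b))
  list(b = b, a = bf$a, padlen = 3L * (spec$order + 1L))
}

# forward-backward (zero-phase) filtering of window columns
filtfilt_cols <- function(coefs, x) {
  .bc_filtfilt_mat(coefs$b, coefs$a, x, coefs$padlen)
}

#' Resample a breathing signal to a uniform rate
#'
#' Surface scanners deliver irregular sampling (Catalyst ~13 Hz, Sentinel
#' ~24 Hz); all processing downstream assumes a uniform 20 Hz grid. Linear
#' interpolation is used: inter-sample intervals are short relative to a
#' breathing period, and linear interpolation cannot ring.
#'
#' @param sig A `breathing_signal` with at least 2 samples.
#' @param rate_hz Target rate in Hz (default 20).
#' @return A uniformly sampled `breathing_signal` spanning the original trace.
#' @export
resample_signal <- function(sig, rate_hz = 20) {
  if (nrow(sig) < 2) {
    bc_abort("bc_invalid_signal", "need at least 2 samples to resample.")
  }
  t0 <- sig$time_s[1]
  t1 <- sig$time_s[nrow(sig)]
  n <- floor((t1 - t0) * rate_hz + 1e-9)
  grid <- t0 + (0:n) / rate_hz
  y <- approx(sig$time_s, sig$pos_mm, xout = grid)$y
  meta <- signal_meta(sig)
  meta$resampled_hz <- rate_hz
  signal_like(sig, grid, y, rate_hz = rate_hz, meta = meta)
}

#' Crop a breathing signal to a time interval
#'
#' Removes setup artefacts at the start or end of an acquisition. The crop
#' bounds are user-supplied; no artefact detection is attempted.
#'
#' @param sig A `breathing_signal`.
#' @param t_start,t_end Interval bounds in seconds (`t_start < t_end`);
#'   samples with `t_start <= t <= t_end` are kept.
#' @return The cropped `breathing_signal`; metadata records the crop.
#' @export
crop_signal <- function(sig, t_start, t_end) {
  if (t_start >= t_end) {
    bc_abort("bc_invalid_signal", "t_start must be below t_end.")
  }
  keep <- sig$time_s >= t_start & sig$time_s <= t_end
  if (!any(keep)) {
    bc_abort("bc_invalid_signal", "crop interval contains no samples.")
  }
  meta <- signal_meta(sig)
  meta$crop <- c(t_start = t_start, t_end = t_end)
  signal_like(sig, sig$time_s[keep], sig$pos_mm[keep], meta = meta)
}

#' Low-pass filter a breathing signal
#'
#' Applies the Butterworth filter of `spec` to a uniformly sampled trace.
#' Zero-phase mode runs the filter forward and backward with odd-reflection
#' padding and steady-state initial conditions, so the pass leaves no phase
#' lag and no start-up transient; causal mode runs forward only and does lag.
#'
#' @param sig A uniformly sampled `breathing_signal`.
#' @param spec A [filter_spec()].
#' @return The filtered `breathing_signal`.
#' @export
lowpass_signal <- function(sig, spec = filter_spec()) {
  rate <- signal_rate(sig)
  if (is.null(rate)) {
    bc_abort("bc_invalid_signal",
             "signal must be uniformly sampled (resample first).")
  }
  coefs <- butter_coefs(spec, rate)
  y <- if (spec$mode == "zero_phase") {
    filtfilt_cols(coefs, matrix(sig$pos_mm, ncol = 1))[, 1]
  } else {
    as.vector(.bc_filter_causal(coefs$b, coefs$a, sig$pos_mm))
  }
  meta <- signal_meta(sig)
  meta$filter <- sprintf("butterworth order %d, %.3g Hz, %s",
                         spec$order, spec$cutoff_hz, spec$mode)
  signal_like(sig, sig$time_s, y, meta = meta)
}

#' Standard preprocessing pipeline
#'
#' Resample to a uniform rate, optionally crop, then zero-phase low-pass
#' filter -- the canonical preparation of a raw surrogate trace before
#' decomposition and training.
#'
#' @param sig A `breathing_signal`.
#' @param rate_hz Target sampling rate (Hz).
#' @param crop Optional numeric length-2 vector `c(t_start, t_end)` in seconds.
#' @param spec A [filter_spec()].
#' @return A preprocessed `breathing_signal`.
#' @export
preprocess_signal <- function(sig, rate_hz = 20, crop = NULL,
                              spec = filter_spec()) {
  out <- resample_signal(sig, rate_hz)
  if (!is.null(crop)) out <- crop_signal(out, crop[1], crop[2])
  lowpass_signal(out, spec)
}
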