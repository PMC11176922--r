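#' Dynamic window scaling parameters
#'
#' Each input window is normalised by its own extremes: with window minimum
#' \eqn{y_{min}}, maximum \eqn{y_{max}} and half-range
#' \eqn{y_{50\%} = (y_{max}-y_{min})/2}, the affine map
#' \eqn{(y - y_{min} - y_{50\%})/y_{50\%}} sends the window exactly onto
#' \eqn{[-1, 1]}. This removes the absolute amplitude from the learning
#' problem so that shallow and deep breathers share one model.
#'
#' @param window Numeric vector of displacements (mm) in one input window.
#' @return A `bc_window_scaling` list with `y_min`, `y_max`, `y_half` (mm).
#' @export
window_params <- function(window) {
  if (length(window) == 0 || anyNA(window)) {
    bc_abort("bc_degenerate_window", "window is empty or contains NA.")
  }
  y_min <- min(window)
  y_max <- max(window)
  if (!(y_max > y_min)) {
    bc_abort("bc_degenerate_window", "window has zero range.")
  }
  structure(list(y_min = y_min, y_max = y_max, y_half = (y_max - y_min) / 2),
            class = "bc_window_scaling")
}

#' Scale displacements into the window's [-1, 1] range
#'
#' @param y Displacements in mm.
#' @param p A [window_params()] result.
#' @return Dimensionless values; the window extremes map to -1 and +1.
#' @export
scale_signal <- function(y, p) {
  (y - p$y_min - p$y_half) / p$y_half
}

#' Invert the window scaling
#'
#' @param values Dimensionless scaled values.
#' @param p A [window_params()] result.
#' @return Displacements in mm; exact inverse of [scale_signal()].
#' @export
unscale_signal <- function(values, p) {
  values * p$y_half + p$y_min + p$y_half
}

#' Scale cyclic components into network channels
#'
#' Encodes the three decomposition channels with the same window parameters
#' used for the signal: the deflection divides by the half-range, the
#' baseline gets the full affine map, and the wrapped phase maps linearly
#' from \[0, 360) to \[-1, 1). The encoding is affine-consistent: summing the
#' scaled model terms
#' \eqn{d_s + d_s\cos\varphi + BL_s} reproduces [scale_signal()] of the
#' reassembled signal exactly, which is what lets the component model train
#' in scaled space and predict in millimetres.
#'
#' With `phase_encoding = "unwrapped_delta"` the phase channel instead
#' encodes the signed phase advance beyond a reference phase `phase_ref`
#' (degrees, typically the phase estimated at the window end), wrapped to
#' (-180, 180\] and mapped to (-1, 1\]; this removes the wrap discontinuity
#' from the regression target (a 500 ms advance is a small positive number)
#' at the cost of needing the same reference at decode time.
#'
#' @param phase_deg Phase in degrees.
#' @param deflection_mm Deflection in mm, non-negative.
#' @param baseline_mm Baseline in mm.
#' @param p A [window_params()] result.
#' @param phase_encoding `"wrapped_linear"` (default) or `"unwrapped_delta"`.
#' @param phase_ref Reference phase in degrees (required for
#'   `"unwrapped_delta"`).
#' @return A list with `phase`, `deflection`, `baseline` channel values.
#' @export
scale_components <- function(phase_deg, deflection_mm, baseline_mm, p,
                             phase_encoding = c("wrapped_linear",
                                                "unwrapped_delta"),
                             phase_ref = NULL) {
  phase_encoding <- match.arg(phase_encoding)
  if (any(deflection_mm < 0, na.rm = TRUE)) {
    bc_abort("bc_invalid_components", "deflection must be non-negative.")
  }
  phase <- if (phase_encoding == "wrapped_linear") {
    wrap360(phase_deg) / 180 - 1
  } else {
    if (is.null(phase_ref)) {
      bc_abort("bc_invalid_components",
               "phase_ref is required for unwrapped_delta encoding.")
    }
    wrap180(phase_deg - phase_ref) / 180
  }
  list(
    phase = phase,
    deflection = deflection_mm / p$y_half,
    baseline = (baseline_mm - p$y_min - p$y_half) / p$y_half
  )
}

#' Decode network channels back to cyclic components
#'
#' Inverse of [scale_components()]. Deflection may come back slightly
#' negative from an imperfect regressor; it is returned as-is so callers can
#' decide how to clamp.
#'
#' @param channels List or 3-column matrix of `phase`, `deflection`,
#'   `baseline` channel values.
#' @inheritParams scale_components
#' @return A list with `phase_deg` (wrapped to \[0, 360)), `deflection_mm`,
#'   `baseline_mm`.
#' @export
decode_components <- function(channels, p,
                              phase_encoding = c("wrapped_linear",
                                                 "unwrapped_delta"),
                              phase_ref = NULL) {
  phase_encoding <- match.arg(phase_encoding)
  if (is.matrix(channels)) {
    channels <- list(phase = channels[, 1], deflection = channels[, 2],
                     baseline = channels[, 3])
  }
  phase <- if (phase_encoding == "wrapped_linear") {
    (channels$phase + 1) * 180
  } else {
    if (is.null(phase_ref)) {
      bc_abort("bc_invalid_components",
               "phase_ref is required for unwrapped_delta encoding.")
    }
    channels$phase * 180 + phase_ref
  }
  list(
    phase_deg = wrap360(phase),
    deflection_mm = channels$deflection * p$y_half,
    baseline_mm = channels$baseline * p$y_half + p$y_min + p$y_half
  )
}

wrap360 <- function(x) x - 360 * floor(x / 360)

# signed wrap into (-180, 180]
wrap180 <- function(x) {
  w <- wrap360(x)
  ifelse(w > 180, w - 360, w)
}
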