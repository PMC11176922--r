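#' Envelope and midline curves of a breathing trace
#'
#' Piecewise-linear interpolation through the signal values at the upper
#' anchors gives the peak-inhalation curve, through the lower anchors the
#' baseline; the midline (the 50%-inhalation level) is their mean. No
#' extrapolation beyond the anchor spans is performed.
#'
#' @param sig A uniformly sampled, filtered `breathing_signal`.
#' @param peaks A [detect_peaks()] result for `sig`.
#' @return A tibble with `time_s`, `upper_mm`, `baseline_mm`, `midline_mm`
#'   and `valid` (TRUE strictly between the first and last anchor, where both
#'   envelopes are defined).
#' @export
build_envelopes <- function(sig, peaks) {
  anchors <- peaks$anchors
  if (length(peaks$upper_idx) < 1 || length(peaks$lower_idx) < 1 ||
      nrow(anchors) < 2) {
    bc_abort("bc_insufficient_peaks",
             "need at least one upper and one lower anchor.")
  }
  t <- sig$time_s
  interp_nodes <- function(idx) {
    if (length(idx) == 1) {
      out <- rep(NA_real_, length(t))
      out[idx] <- sig$pos_mm[idx]
      out
    } else {
      approx(t[idx], sig$pos_mm[idx], xout = t, rule = 1)$y
    }
  }
  upper <- interp_nodes(peaks$upper_idx)
  lower <- interp_nodes(peaks$lower_idx)
  first_a <- min(anchors$idx)
  last_a <- max(anchors$idx)
  inside <- seq_along(t) > first_a & seq_along(t) < last_a
  valid <- inside & !is.na(upper) & !is.na(lower)
  tibble::tibble(
    time_s = t,
    upper_mm = upper,
    baseline_mm = lower,
    midline_mm = (upper + lower) / 2,
    valid = valid
  )
}

#' Decompose a breathing signal into phase, deflection and baseline
#'
#' Inverts the modulated-cosine model
#' \deqn{y(t) = d(t) + d(t)\cos\varphi(t) + BL(t)}
#' sample by sample: the deflection \eqn{d} is the midline minus the
#' baseline (one-half of the local breathing amplitude), the baseline
#' \eqn{BL} is the lower envelope, and the phase follows from
#' \eqn{\cos\varphi = (y - d - BL)/d}, taking the \eqn{[0°,180°]} branch on
#' descending half-cycles (upper to lower anchor) and \eqn{360° - \arccos}
#' on ascending ones. The arccos argument is clamped to \eqn{[-1, 1]} and the
#' per-half-cycle phase progression is forced non-decreasing; samples touched
#' by either correction carry `clamped = TRUE` (on such samples the exact
#' reassembly identity no longer holds).
#'
#' Upper anchors carry phase exactly 0 deg, lower anchors exactly 180 deg;
#' the unwrapped phase advances 360 deg per completed breathing cycle.
#'
#' @param sig A uniformly sampled, filtered `breathing_signal`.
#' @param peaks A [detect_peaks()] result; computed from `sig` when omitted.
#' @param threshold_frac Passed to [detect_peaks()] when `peaks` is omitted.
#' @return A `bc_decomp` tibble: `time_s`, `pos_mm`, `phase_deg` (wrapped to
#'   \[0, 360)), `phase_unwrapped_deg`, `deflection_mm`, `baseline_mm`,
#'   `midline_mm`, `valid`, `clamped`; the peak set, sampling rate and signal
#'   metadata ride along as attributes.
#' @export
decompose_signal <- function(sig, peaks = NULL, threshold_frac = 0.55) {
  if (is.null(peaks)) peaks <- detect_peaks(sig, threshold_frac)
  env <- build_envelopes(sig, peaks)
  n <- nrow(sig)
  y <- sig$pos_mm
  d <- env$midline_mm - env$baseline_mm
  bl <- env$baseline_mm
  if (any(d[env$valid] <= 0)) {
    bc_abort("bc_degenerate_envelope",
             "non-positive deflection inside the valid region.")
  }

  anchors <- peaks$anchors
  m <- nrow(anchors)
  phase_u <- rep(NA_real_, n)
  clamped <- rep(FALSE, n)

  # unwrapped phase at each anchor: 180 deg per half-cycle, upper == 0 mod 360
  base <- (seq_len(m) - 1) * 180 + if (anchors$type[1] == 1L) 0 else 180
  phase_u[anchors$idx] <- base

  any_hard_clamp <- FALSE
  for (j in seq_len(m - 1)) {
    i0 <- anchors$idx[j]
    i1 <- anchors$idx[j + 1]
    if (i1 - i0 < 2) next
    span <- (i0 + 1):(i1 - 1)
    cc <- (y[span] - d[span] - bl[span]) / d[span]
    # envelopes are one-sided around the outermost anchors: no phase there
    if (!all(is.finite(cc))) next
    out_of_range <- abs(cc) > 1
    if (any(abs(cc) > 1.001)) any_hard_clamp <- TRUE
    cc <- pmin(1, pmax(-1, cc))
    prog <- if (anchors$type[j] == 1L) {
      acos(cc) * (180 / pi)          # descending: 0 -> 180
    } else {
      180 - acos(cc) * (180 / pi)    # ascending: (360 - acos) - 180
    }
    mono <- cummax(prog)
    clamped[span] <- out_of_range | (mono - prog > 1e-9)
    phase_u[span] <- base[j] + mono
  }
  if (any_hard_clamp) {
    warn("arccos argument beyond [-1.001, 1.001]: envelope inconsistency.",
         class = "bc_clamp_warning")
  }

  phase_w <- phase_u - 360 * floor(phase_u / 360)
  # anchors exact by construction
  phase_w[anchors$idx] <- ifelse(anchors$type == 1L, 0, 180)

  outside <- is.na(phase_u)
  d[outside] <- NA_real_
  valid <- env$valid & !outside

  dec <- tibble::new_tibble(
    list(
      time_s = sig$time_s,
      pos_mm = y,
      phase_deg = phase_w,
      phase_unwrapped_deg = phase_u,
      deflection_mm = d,
      baseline_mm = bl,
      midline_mm = env$midline_mm,
      valid = valid,
      clamped = clamped
    ),
    nrow = n,
    class = "bc_decomp",
    peaks = peaks,
    rate_hz = signal_rate(sig),
    meta = signal_meta(sig)
  )
  dec
}

#' Reassemble a breathing signal from cyclic components
#'
#' Evaluates the modulated-cosine model \eqn{y = d + d\cos\varphi + BL}
#' elementwise. This is the exact inverse of [decompose_signal()] on valid,
#' unclamped samples.
#'
#' @param phase_deg Phase in degrees, or a `bc_decomp` tibble (in which case
#'   the remaining arguments are taken from its columns).
#' @param deflection_mm Deflection in mm, all non-negative.
#' @param baseline_mm Baseline in mm.
#' @return Numeric vector of displacements in mm.
#' @examples
#' reassemble_signal(0, 3, 1)    # 7: full inhale
#' reassemble_signal(180, 3, 1)  # 1: full exhale
#' @export
reassemble_signal <- function(phase_deg, deflection_mm = NULL,
                              baseline_mm = NULL) {
  if (is.data.frame(phase_deg)) {
    dec <- phase_deg
    phase_deg <- dec$phase_deg
    deflection_mm <- dec$deflection_mm
    baseline_mm <- dec$baseline_mm
  }
  if (any(deflection_mm < 0, na.rm = TRUE)) {
    bc_abort("bc_invalid_components", "deflection must be non-negative.")
  }
  deflection_mm + deflection_mm * cospi(phase_deg / 180) + baseline_mm
}

#' Peak set attached to a decomposition
#' @param dec A `bc_decomp`.
#' @return The `bc_peaks` object used for the decomposition.
#' @export
decomp_peaks <- function(dec) attr(dec, "peaks")
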