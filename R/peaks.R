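#' Detect respiratory extrema
#'
#' Finds the alternating inhale/exhale anchor points of a filtered breathing
#' trace. All interior local extrema are collected first (the first sample of
#' a plateau counts as the extremum) and collapsed to an alternating
#' max/min sequence, keeping the more extreme of same-sign neighbours. The
#' mean peak-to-trough amplitude is then estimated from the swings between
#' consecutive alternating extrema, and the adjacent pair with the smallest
#' swing is deleted while that swing falls below `threshold_frac` of the
#' running mean amplitude. Deleting a min/max pair preserves alternation, so
#' small wiggles riding on a breathing cycle are pruned without ever
#' discarding the cycle's true extrema; the mean amplitude is re-estimated
#' after every deletion until the retained set is stable.
#'
#' Phase-0 deg anchors are assigned to the local *maxima* of the trace so the
#' modulated-cosine model holds with positive deflection and the baseline
#' equal to the lower envelope; use `flip_sign` upstream if the acquisition
#' device reports the opposite polarity.
#'
#' @param sig A uniformly sampled, filtered `breathing_signal` covering at
#'   least two breathing cycles.
#' @param threshold_frac Fraction of the mean breathing amplitude below which
#'   a swing between adjacent extrema is pruned (default 0.55).
#' @return A `bc_peaks` object: tibble of anchors (`idx`, `time_s`, `pos_mm`,
#'   `type` +1 for upper / -1 for lower) with fields `upper_idx`,
#'   `lower_idx`, `threshold_frac` and `mean_amplitude_mm`.
#' @export
detect_peaks <- function(sig, threshold_frac = 0.55) {
  y <- sig$pos_mm
  ext <- local_extrema(y)
  if (nrow(ext) < 2) {
    bc_abort("bc_no_peaks", "no alternating extrema found.")
  }
  ext <- enforce_alternation(ext, y)
  for (iter in seq_len(nrow(ext))) {
    if (nrow(ext) < 2) bc_abort("bc_no_peaks", "no alternating extrema found.")
    swings <- abs(diff(y[ext$idx]))
    mean_amp <- mean(swings)
    k <- which.min(swings)
    if (swings[k] >= threshold_frac * mean_amp) break
    ext <- ext[-c(k, k + 1L), , drop = FALSE]
  }
  ext <- enforce_alternation(ext, y)
  if (nrow(ext) < 2 || !any(ext$type == 1L) || !any(ext$type == -1L)) {
    bc_abort("bc_no_peaks", "no alternating extrema found.")
  }
  anchors <- tibble::tibble(
    idx = ext$idx,
    time_s = sig$time_s[ext$idx],
    pos_mm = y[ext$idx],
    type = ext$type
  )
  structure(
    list(
      anchors = anchors,
      upper_idx = anchors$idx[anchors$type == 1L],
      lower_idx = anchors$idx[anchors$type == -1L],
      threshold_frac = threshold_frac,
      mean_amplitude_mm = mean(abs(diff(anchors$pos_mm)))
    ),
    class = "bc_peaks"
  )
}

#' @export
print.bc_peaks <- function(x, ...) {
  cat(sprintf(
    "# %d upper / %d lower anchors, mean amplitude %.2f mm (threshold %.0f%%)\n",
    length(x$upper_idx), length(x$lower_idx), x$mean_amplitude_mm,
    100 * x$threshold_frac))
  print(x$anchors, ...)
  invisible(x)
}

# Interior local extrema; the first sample of a plateau is the extremum.
local_extrema <- function(y) {
  dy <- diff(y)
  s <- sign(dy)
  nz <- which(s != 0)
  empty <- tibble::tibble(idx = integer(), type = integer())
  if (length(nz) < 2) return(empty)
  sv <- s[nz]
  chg <- which(sv[-1] != sv[-length(sv)])
  if (length(chg) == 0) return(empty)
  tibble::tibble(
    idx = nz[chg] + 1L,
    type = ifelse(sv[chg] > 0, 1L, -1L)
  )
}

# Collapse runs of same-sign extrema, keeping the most extreme (ties: first).
enforce_alternation <- function(ext, y) {
  if (nrow(ext) == 0) return(ext)
  r <- rle(ext$type)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pick <- integer(length(r$lengths))
  for (k in seq_along(r$lengths)) {
    run <- starts[k]:ends[k]
    vals <- y[ext$idx[run]]
    pick[k] <- run[if (r$values[k] > 0) which.max(vals) else which.min(vals)]
  }
  ext[pick, , drop = FALSE]
}
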