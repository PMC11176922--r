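#' Build training samples from a decomposed trace
#'
#' Slides an input window over the trace and pairs it with the value(s) one
#' prediction horizon beyond the window end. Only windows whose samples --
#' and whose target -- lie on the valid region of the decomposition are
#' used. Each window is filtered (zero-phase, within the window only, the
#' same operation applied at inference) and scaled by its own
#' [window_params()]; targets are scaled with the *input window's* parameters,
#' never with information from the future. Windows with zero range are
#' skipped and counted.
#'
#' @param dec A `bc_decomp` from [decompose_signal()].
#' @param config A [predictor_config()].
#' @param stride Window start increment in samples (1 = every sample).
#' @param window_filter Apply the per-window zero-phase filter (default TRUE).
#' @param fspec [filter_spec()] for the per-window filter.
#' @return A `bc_samples` object: input matrix `X` (windows x samples),
#'   target matrix `Y` (1 column in signal mode, 3 in components mode),
#'   per-window scaling tibble, target indices/times, and the number of
#'   windows skipped as degenerate. Empty (zero-row) when the trace is
#'   shorter than window + horizon.
#' @export
make_samples <- function(dec, config, stride = 1L, window_filter = TRUE,
                         fspec = filter_spec()) {
  W <- config$window_samples
  h <- config$horizon_samples
  n <- nrow(dec)
  rate <- attr(dec, "rate_hz")
  empty <- function() {
    structure(list(
      X = matrix(numeric(), 0, W),
      Y = matrix(numeric(), 0,
                 if (config$output_mode == "components") 3L else 1L),
      scaling = tibble::tibble(y_min = double(), y_max = double(),
                               y_half = double()),
      target_idx = integer(), t_target = double(),
      phase_ref = double(), n_skipped = 0L, config = config
    ), class = "bc_samples")
  }
  if (n < W + h) return(empty())

  ok <- dec$valid
  bad_cum <- cumsum(!ok)
  starts <- seq.int(1L, n - W - h + 1L, by = stride)
  # window [s, s+W-1] entirely valid and target s+W-1+h valid
  win_ok <- (bad_cum[starts + W - 1L] - c(0L, bad_cum)[starts]) == 0L
  tgt_ok <- ok[starts + W - 1L + h]
  starts <- starts[win_ok & tgt_ok]
  if (length(starts) == 0) return(empty())

  idx <- outer(0:(W - 1L), starts, `+`)       # W x n_win
  Xw <- matrix(dec$pos_mm[idx], nrow = W)
  if (window_filter) {
    coefs <- butter_coefs(fspec, rate)
    Xw <- filtfilt_cols(coefs, Xw)
  }
  y_min <- apply(Xw, 2, min)
  y_max <- apply(Xw, 2, max)
  degen <- !(y_max - y_min > 1e-9)
  n_skipped <- sum(degen)
  if (any(degen)) {
    starts <- starts[!degen]
    Xw <- Xw[, !degen, drop = FALSE]
    y_min <- y_min[!degen]
    y_max <- y_max[!degen]
  }
  if (length(starts) == 0) {
    out <- empty()
    out$n_skipped <- n_skipped
    return(out)
  }
  y_half <- (y_max - y_min) / 2
  Xs <- t((Xw - rep(y_min + y_half, each = W)) / rep(y_half, each = W))

  tgt <- starts + W - 1L + h
  phase_ref <- rep(NA_real_, length(starts))
  if (config$output_mode == "components") {
    if (config$phase_encoding == "unwrapped_delta") {
      phase_ref <- window_end_phase(Xw, threshold_frac = 0.55)
      usable <- !is.na(phase_ref)
      starts <- starts[usable]; tgt <- tgt[usable]
      Xs <- Xs[usable, , drop = FALSE]
      y_min <- y_min[usable]; y_max <- y_max[usable]; y_half <- y_half[usable]
      phase_ref <- phase_ref[usable]
      if (length(starts) == 0) {
        out <- empty(); out$n_skipped <- n_skipped; return(out)
      }
    }
    Y <- matrix(NA_real_, length(starts), 3)
    for (k in seq_along(starts)) {
      p <- list(y_min = y_min[k], y_max = y_max[k], y_half = y_half[k])
      ch <- scale_components(dec$phase_deg[tgt[k]],
                             dec$deflection_mm[tgt[k]],
                             dec$baseline_mm[tgt[k]], p,
                             phase_encoding = config$phase_encoding,
                             phase_ref = phase_ref[k])
      Y[k, ] <- c(ch$phase, ch$deflection, ch$baseline)
    }
  } else {
    Y <- matrix((dec$pos_mm[tgt] - y_min - y_half) / y_half, ncol = 1)
  }

  structure(list(
    X = Xs, Y = Y,
    scaling = tibble::tibble(y_min = y_min, y_max = y_max, y_half = y_half),
    target_idx = tgt,
    t_target = dec$time_s[tgt],
    phase_ref = phase_ref,
    n_skipped = n_skipped,
    config = config
  ), class = "bc_samples")
}

#' @export
print.bc_samples <- function(x, ...) {
  cat(sprintf("# %d samples (window %d, horizon %d, %s mode), %d skipped\n",
              nrow(x$X), x$config$window_samples, x$config$horizon_samples,
              x$config$output_mode, x$n_skipped))
  invisible(x)
}

# Estimate the wrapped phase at the last sample of each window column using
# only the window itself. Two estimators are combined: inverting the cosine
# model with envelopes frozen at the last anchor (well-conditioned mid-cycle,
# where the cosine is steep) and the phase advance since the last anchor at
# the window's recent half-cycle rate (robust near the extrema, where the
# arccos is ill-conditioned). NA when the window shows no anchors.
window_end_phase <- function(Xw, threshold_frac = 0.55) {
  vapply(seq_len(ncol(Xw)), function(j) {
    w <- Xw[, j]
    n <- length(w)
    sig <- new_breathing_signal(seq_len(n), w, 1, list())
    pk <- tryCatch(detect_peaks(sig, threshold_frac), error = function(e) NULL)
    if (is.null(pk)) return(NA_real_)
    a <- pk$anchors
    last_idx <- a$idx[nrow(a)]
    base <- if (a$type[nrow(a)] == 1L) 0 else 180

    gaps <- diff(a$idx)
    half_T <- if (length(gaps)) mean(tail(gaps, 4)) else NA_real_
    timing <- if (is.finite(half_T)) {
      base + min(180 * (n - last_idx) / half_T, 179.5)
    } else NA_real_

    upper <- node_interp(pk$upper_idx, w, n)
    lower <- node_interp(pk$lower_idx, w, n)
    d <- (upper - lower) / 2
    amp <- NA_real_
    cc <- NA_real_
    if (is.finite(d) && d > 0) {
      cc <- max(-1, min(1, (w[n] - d - lower) / d))
      prog <- if (a$type[nrow(a)] == 1L) acos(cc) * (180 / pi)
              else 180 - acos(cc) * (180 / pi)
      amp <- base + prog
    }
    est <- if (is.finite(amp) && is.finite(cc) && abs(cc) <= 0.8) amp
           else if (is.finite(timing)) timing
           else amp
    if (!is.finite(est)) NA_real_ else wrap360(est)
  }, numeric(1))
}

node_interp <- function(idx, w, at) {
  if (length(idx) == 0) return(NA_real_)
  if (length(idx) == 1) return(w[idx])
  approx(idx, w[idx], xout = at, rule = 2)$y
}

#' Split datasets into training and validation at the subject level
#'
#' All traces of one subject end up on the same side of the split so
#' validation measures generalisation to unseen subjects. Subjects are
#' shuffled deterministically under `seed` and assigned to the validation
#' side while that brings its dataset count closer to the requested
#' proportion.
#'
#' @param datasets A tibble with one row per dataset and a `subject` column,
#'   or a vector of per-dataset subject ids.
#' @param val_fraction Target fraction of datasets on the validation side
#'   (default 1/5, i.e. a 4:1 split).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list with `train` and `val` (row indices into `datasets`).
#' @export
split_train_val <- function(datasets, val_fraction = 0.2, seed = 1) {
  subjects <- if (is.data.frame(datasets)) datasets$subject else datasets
  n <- length(subjects)
  if (n < 5) {
    bc_abort("bc_invalid_split", "need at least 5 datasets for a 4:1 split.")
  }
  target <- val_fraction * n
  uniq <- unique(subjects)
  order_u <- withr::with_seed(seed, sample(length(uniq)))
  val_subj <- character(0)
  cur <- 0
  for (s in uniq[order_u]) {
    cnt <- sum(subjects == s)
    if (abs(cur + cnt - target) < abs(cur - target)) {
      val_subj <- c(val_subj, as.character(s))
      cur <- cur + cnt
    }
  }
  val <- which(as.character(subjects) %in% val_subj)
  if (length(val) == 0) { # degenerate targets: force one subject over
    val <- which(subjects == uniq[order_u[1]])
  }
  list(train = setdiff(seq_len(n), val), val = val)
}
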