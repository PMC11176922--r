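# Independent oracles and small fixture builders used across the suite.

# Pure-R double-precision stacked-LSTM forward pass: the reference the C++
# kernel is checked against. Deliberately written loop-per-step with no
# shared code.
ref_lstm_forward <- function(params, X) {
  L <- length(params$W)
  B <- nrow(X)
  T_ <- ncol(X)
  sig <- function(x) 1 / (1 + exp(-x))
  inp <- lapply(seq_len(T_), function(t) X[, t, drop = FALSE])
  hs <- NULL
  for (l in seq_len(L)) {
    u <- nrow(params$U[[l]])
    h <- matrix(0, B, u)
    c <- matrix(0, B, u)
    hs <- vector("list", T_)
    for (t in seq_len(T_)) {
      A <- inp[[t]] %*% params$W[[l]] + h %*% params$U[[l]] +
        matrix(params$b[[l]], B, 4 * u, byrow = TRUE)
      gi <- sig(A[, 1:u, drop = FALSE])
      gf <- sig(A[, (u + 1):(2 * u), drop = FALSE])
      gg <- tanh(A[, (2 * u + 1):(3 * u), drop = FALSE])
      go <- sig(A[, (3 * u + 1):(4 * u), drop = FALSE])
      c <- gf * c + gi * gg
      h <- go * tanh(c)
      hs[[t]] <- h
    }
    inp <- hs
  }
  hs[[T_]] %*% params$Wd + matrix(params$bd, B, ncol(params$Wd), byrow = TRUE)
}

# Magnitude response of the designed digital filter at frequency f_hz;
# a forward-backward pass has gain |H|^2.
filter_gain <- function(spec, rate_hz, f_hz) {
  bf <- signal::butter(spec$order, 2 * spec$cutoff_hz / rate_hz, type = "low")
  z <- exp(-1i * 2 * pi * f_hz / rate_hz * seq(0, length(bf$b) - 1))
  abs(sum(bf$b * z) / sum(bf$a * z))
}

# raised cosine y = off + amp * cos(2 pi t / period) on a uniform grid
cosine_signal <- function(duration_s = 60, rate_hz = 20, period_s = 4,
                          amp = 5, off = 5) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  breathing_signal(t, off + amp * cospi(2 * t / period_s), rate_hz = rate_hz)
}

# decomposition of a filtered synthetic trace plus its generator output
synth_decomp <- function(cfg) {
  tr <- generate_trace(cfg)
  f <- lowpass_signal(tr$signal)
  list(trace = tr, filtered = f,
       dec = suppressWarnings(decompose_signal(f)))
}

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
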