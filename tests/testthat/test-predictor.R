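tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(window_samples = 20, horizon_samples = 10, lstm_units = c(6, 6, 6),
         learning_rate = 0.01, batch_size = 64, epochs = 10, seed = 1),
    list(...)
  )
  do.call(predictor_config, args)
}

manual_samples <- function(n, w, n_out = 1, seed = 1, const = NULL) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * w, -1, 1), n, w)
    Y <- if (is.null(const)) matrix(rnorm(n * n_out), n, n_out)
         else matrix(const, n, n_out)
    structure(list(X = X, Y = Y,
                   scaling = tibble::tibble(y_min = rep(-1, n),
                                            y_max = rep(1, n),
                                            y_half = rep(1, n)),
                   target_idx = seq_len(n), t_target = seq_len(n) / 20,
                   phase_ref = rep(NA_real_, n), n_skipped = 0L,
                   config = NULL),
              class = "bc_samples")
  })
}

test_that("the network forward pass matches an independent R reference", {
  p <- withr::with_seed(2, breathecast:::init_lstm_params(c(5, 4, 3), 1, 3))
  X <- withr::with_seed(3, matrix(rnorm(7 * 12), 7, 12))
  got <- breathecast:::forward_chunks(p, X)
  want <- ref_lstm_forward(p, X)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("analytic gradients agree with finite differences of the reference loss", {
  p <- withr::with_seed(4, breathecast:::init_lstm_params(c(4, 4), 1, 2))
  X <- withr::with_seed(5, matrix(rnorm(6 * 10), 6, 10))
  Y <- withr::with_seed(6, matrix(rnorm(6 * 2), 6, 2))
  g <- breathecast:::.bc_lstm_grad(p, X, Y)
  expect_lt(abs(g$loss - mean((ref_lstm_forward(p, X) - Y)^2)), 1e-6)
  eps <- 1e-6
  numgrad <- function(mutate) {
    (mean((ref_lstm_forward(mutate(p, eps), X) - Y)^2) -
       mean((ref_lstm_forward(mutate(p, -eps), X) - Y)^2)) / (2 * eps)
  }
  cases <- list(
    list(get = function(g) g$grads$W[[1]][1, 2],
         mut = function(p, e) { p$W[[1]][1, 2] <- p$W[[1]][1, 2] + e; p }),
    list(get = function(g) g$grads$U[[2]][2, 5],
         mut = function(p, e) { p$U[[2]][2, 5] <- p$U[[2]][2, 5] + e; p }),
    list(get = function(g) g$grads$b[[1]][1, 7],
         mut = function(p, e) { p$b[[1]][1, 7] <- p$b[[1]][1, 7] + e; p }),
    list(get = function(g) g$grads$Wd[3, 1],
         mut = function(p, e) { p$Wd[3, 1] <- p$Wd[3, 1] + e; p })
  )
  for (cs in cases) {
    expect_lt(abs(numgrad(cs$mut) - cs$get(g)), 1e-4)
  }
})

test_that("a constant target is learned to near-zero loss within 50 epochs", {
  cfg <- predictor_config(window_samples = 15, horizon_samples = 1,
                          lstm_units = c(4, 4, 4), learning_rate = 0.01,
                          batch_size = 128, epochs = 50, seed = 2)
  s <- manual_samples(128, 15, const = 0.37)
  m <- fit_predictor(s, config = cfg)
  expect_lt(m$history$loss[nrow(m$history)], 1e-4)
})

test_that("training is deterministic under the seed and survives persistence bit-exactly", {
  cfg <- tiny_cfg(epochs = 3)
  s <- manual_samples(100, 20)
  m1 <- fit_predictor(s, config = cfg)
  m2 <- fit_predictor(s, config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  path <- withr::local_tempfile(fileext = ".rds")
  save_predictor(m1, path)
  m3 <- load_predictor(path)
  w <- withr::with_seed(8, runif(20, 0, 10))
  expect_identical(predict_window(m1, w), predict_window(m3, w))
})

test_that("predictions align exactly one horizon past the window end", {
  cfg <- tiny_cfg(epochs = 2)
  tr <- generate_trace(synth_config(duration_s = 60, noise_sd_mm = 0,
                                    seed = 5))
  dec <- suppressWarnings(decompose_signal(lowpass_signal(tr$signal)))
  s <- make_samples(dec, cfg)
  m <- fit_predictor(s, config = cfg)
  p <- predict_stream(m, lowpass_signal(tr$signal))
  first <- which(!is.na(p$y_pred_mm))[1]
  expect_equal(first, cfg$window_samples + cfg$horizon_samples)
  expect_equal(p$time_s[first],
               (cfg$window_samples + cfg$horizon_samples - 1) / 20)
  expect_equal(nrow(p), nrow(tr$signal))
})

test_that("component-mode output obeys the modulated-cosine identity", {
  cfg <- tiny_cfg(output_mode = "components", epochs = 2,
                  phase_encoding = "wrapped_linear")  # 1 s windows hold no anchors
  tr <- generate_trace(synth_config(duration_s = 60, seed = 6))
  dec <- suppressWarnings(decompose_signal(lowpass_signal(tr$signal)))
  m <- fit_predictor(make_samples(dec, cfg), config = cfg)
  p <- predict_stream(m, lowpass_signal(tr$signal))
  ok <- !is.na(p$y_pred_mm)
  lhs <- reassemble_signal(p$phase_pred_deg[ok], p$deflection_pred_mm[ok],
                           p$baseline_pred_mm[ok])
  expect_lt(max(abs(lhs - p$y_pred_mm[ok])), 1e-9)
})

test_that("shape and rate mismatches are rejected; degenerate windows yield NA", {
  cfg <- tiny_cfg(epochs = 1)
  m <- fit_predictor(manual_samples(50, 20), config = cfg)
  expect_error(predict_window(m, rep(1, 19)), class = "bc_shape_error")
  expect_true(is.na(predict_window(m, rep(2, 20))$y_pred_mm))
  irregular <- breathing_signal(cumsum(runif(50, 0.04, 0.06)), rnorm(50))
  expect_error(predict_stream(m, irregular), class = "bc_rate_mismatch")
  sig10 <- breathing_signal(seq(0, 5, 0.1), rnorm(51), rate_hz = 10)
  expect_error(predict_stream(m, sig10), class = "bc_rate_mismatch")
  expect_error(fit_predictor(manual_samples(0, 20), config = cfg),
               class = "bc_no_training_data")
})

test_that("both model families beat persistence on a stationary sinusoid", {
  tr <- generate_trace(synth_config(duration_s = 120, period_sd_s = 0,
                                    amplitude_sd_mm = 0,
                                    amplitude_drift_frac = 0,
                                    baseline_drift_mm = 0, noise_sd_mm = 0.1,
                                    seed = 9))
  f <- lowpass_signal(tr$signal)
  dec <- suppressWarnings(decompose_signal(f))
  pers <- evaluate_prediction(predict_persistence(f, 10), dec, "pers")
  for (mode in c("signal", "components")) {
    cfg <- predictor_config(window_samples = 40, horizon_samples = 10,
                            lstm_units = c(10, 10, 10), learning_rate = 0.01,
                            batch_size = 128, epochs = 12, seed = 3,
                            output_mode = mode,
                            phase_encoding = "wrapped_linear")
    m <- fit_predictor(make_samples(dec, cfg, stride = 2), config = cfg)
    ev <- evaluate_prediction(predict_stream(m, f), dec, mode)
    expect_lt(ev$rmse_y_mm, pers$rmse_y_mm)
  }
})

test_that("the tidy accessors expose history and configuration", {
  cfg <- tiny_cfg(epochs = 2)
  m <- fit_predictor(manual_samples(64, 20), config = cfg)
  expect_equal(nrow(tidy(m)), 2)
  expect_named(tidy(m), c("epoch", "loss", "val_loss"))
  g <- glance(m)
  expect_equal(g$window_samples, 20)
  expect_equal(g$n_train, 64)
  expect_equal(nrow(g), 1)
})
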