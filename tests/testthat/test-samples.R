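make_valid_dec <- function(n, rate = 20) {
  # fully-valid synthetic decomposition for counting tests
  t <- (seq_len(n) - 1) / rate
  phase_u <- 90 * t
  d <- rep(5, n)
  bl <- rep(0, n)
  tibble::new_tibble(
    list(time_s = t, pos_mm = reassemble_signal(phase_u %% 360, d, bl),
         phase_deg = phase_u %% 360, phase_unwrapped_deg = phase_u,
         deflection_mm = d, baseline_mm = bl, midline_mm = d + bl,
         valid = rep(TRUE, n), clamped = rep(FALSE, n)),
    nrow = n, class = "bc_decomp", rate_hz = rate, peaks = NULL,
    meta = list()
  )
}

test_that("sliding-window sample counts follow n - window - horizon + 1", {
  cfg <- predictor_config(window_samples = 160, horizon_samples = 10,
                          epochs = 1)
  expect_equal(nrow(make_samples(make_valid_dec(200), cfg)$X), 31)
  expect_equal(nrow(make_samples(make_valid_dec(169), cfg)$X), 0)
  expect_equal(nrow(make_samples(make_valid_dec(170), cfg)$X), 1)
})

test_that("samples avoid invalid regions and scale targets with the input window", {
  dec <- make_valid_dec(400)
  dec$valid[200] <- FALSE
  cfg <- predictor_config(window_samples = 40, horizon_samples = 10,
                          epochs = 1)
  s <- make_samples(dec, cfg, window_filter = FALSE)
  # no window or target may touch index 200
  bad <- vapply(seq_along(s$target_idx), function(k) {
    start <- s$target_idx[k] - 10 - 39
    200 %in% c(start:(start + 39), s$target_idx[k])
  }, logical(1))
  expect_false(any(bad))
  # target equals the scaled signal value at window-end + horizon
  k <- 5
  p <- list(y_min = s$scaling$y_min[k], y_max = s$scaling$y_max[k],
            y_half = s$scaling$y_half[k])
  expect_equal(s$Y[k, 1], scale_signal(dec$pos_mm[s$target_idx[k]], p))
  # inputs live in [-1, 1] attaining both bounds
  expect_equal(max(s$X[k, ]), 1)
  expect_equal(min(s$X[k, ]), -1)
})

test_that("components-mode targets encode phase, deflection and baseline channels", {
  dec <- make_valid_dec(300)
  cfg <- predictor_config(window_samples = 40, horizon_samples = 10,
                          epochs = 1, output_mode = "components",
                          phase_encoding = "wrapped_linear")
  s <- make_samples(dec, cfg, window_filter = FALSE)
  k <- 10
  p <- list(y_min = s$scaling$y_min[k], y_max = s$scaling$y_max[k],
            y_half = s$scaling$y_half[k])
  i <- s$target_idx[k]
  ch <- scale_components(dec$phase_deg[i], dec$deflection_mm[i],
                         dec$baseline_mm[i], p)
  expect_equal(s$Y[k, ], c(ch$phase, ch$deflection, ch$baseline))
})

test_that("degenerate windows are skipped and counted", {
  dec <- make_valid_dec(120)
  dec$pos_mm[] <- 5
  cfg <- predictor_config(window_samples = 40, horizon_samples = 10,
                          epochs = 1)
  s <- make_samples(dec, cfg, window_filter = FALSE)
  expect_equal(nrow(s$X), 0)
  expect_equal(s$n_skipped, 71)
})

test_that("train/validation split is subject-pure, near 4:1 and deterministic", {
  # 25 subjects contributing 2-8 datasets each, 70 in total
  withr::local_seed(9)
  sizes <- c(rep(2, 14), rep(3, 6), rep(4, 2), 8, 4, 4)
  expect_equal(sum(sizes), 70)
  subjects <- rep(sprintf("V%02d", seq_along(sizes)), times = sizes)
  sp <- split_train_val(subjects, seed = 5)
  expect_equal(length(sp$train) + length(sp$val), 70)
  expect_lte(abs(length(sp$val) - 14), 2)
  expect_length(intersect(subjects[sp$train], subjects[sp$val]), 0)
  sp2 <- split_train_val(subjects, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_val(subjects, seed = 6)))

  # five single-subject datasets: exactly 4:1
  sp5 <- split_train_val(letters[1:5], seed = 1)
  expect_length(sp5$train, 4)
  expect_length(sp5$val, 1)

  expect_error(split_train_val(letters[1:4]), class = "bc_invalid_split")
})
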