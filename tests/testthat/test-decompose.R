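test_that("a raised cosine recovers constant deflection/baseline and linear phase", {
  # y(t) = 5 + 5 cos(90 deg/s * t): the exact model form
  sig <- cosine_signal(60)
  dec <- decompose_signal(sig)
  v <- dec$valid
  expect_gt(sum(v), 1000)
  expect_lt(max(abs(dec$deflection_mm[v] - 5)), 1e-6)
  expect_lt(max(abs(dec$baseline_mm[v])), 1e-6)
  slope <- stats::coef(stats::lm(dec$phase_unwrapped_deg[v] ~ dec$time_s[v]))[[2]]
  expect_lt(abs(slope - 90), 0.09)
})

test_that("envelopes are piecewise linear through the anchors with midline their mean", {
  sig <- cosine_signal(40, amp = 5, off = 5)
  pk <- detect_peaks(sig)
  env <- build_envelopes(sig, pk)
  v <- env$valid
  expect_lt(max(abs(env$upper_mm[v] - 10)), 1e-9)
  expect_lt(max(abs(env$baseline_mm[v])), 1e-9)
  expect_lt(max(abs(env$midline_mm[v] - 5)), 1e-12)

  # amplitude-modulated trace: midline is the mean of the envelopes pointwise
  d <- synth_decomp(synth_config(duration_s = 80, amplitude_sd_mm = 1.5,
                                 noise_sd_mm = 0, seed = 3))
  pk2 <- decomp_peaks(d$dec)
  env2 <- build_envelopes(d$filtered, pk2)
  v2 <- env2$valid
  expect_lt(max(abs(env2$midline_mm[v2] -
                      (env2$upper_mm[v2] + env2$baseline_mm[v2]) / 2)), 1e-12)
  # between two upper anchors the upper envelope is the straight chord
  ui <- pk2$upper_idx
  seg <- ui[3]:ui[4]
  chord <- env2$upper_mm[ui[3]] +
    (env2$upper_mm[ui[4]] - env2$upper_mm[ui[3]]) *
      (seg - ui[3]) / (ui[4] - ui[3])
  expect_lt(max(abs(env2$upper_mm[seg] - chord)), 1e-9)
})

test_that("phase is exact at anchors and non-decreasing on the valid region", {
  for (s in 1:5) {
    d <- synth_decomp(synth_config(duration_s = 90, noise_sd_mm = 0.3,
                                   shape_exponent = (s %% 3) + 1, seed = 10 + s))
    dec <- d$dec
    pk <- decomp_peaks(dec)
    inner_u <- setdiff(pk$upper_idx, range(pk$anchors$idx))
    inner_l <- setdiff(pk$lower_idx, range(pk$anchors$idx))
    expect_true(all(dec$phase_deg[inner_u] == 0))
    expect_true(all(dec$phase_deg[inner_l] == 180))
    pu <- dec$phase_unwrapped_deg[dec$valid]
    expect_true(all(diff(pu) >= 0))
  }
})

test_that("decompose/reassemble round-trips exactly on valid unclamped samples", {
  for (s in 1:5) {
    d <- synth_decomp(synth_config(duration_s = 90, amplitude_sd_mm = 1,
                                   noise_sd_mm = 0.3,
                                   shape_exponent = (s %% 3) + 1, seed = 20 + s))
    ok <- d$dec$valid & !d$dec$clamped
    err <- abs(reassemble_signal(d$dec) - d$dec$pos_mm)
    expect_lt(max(err[ok]), 1e-9)
  }
})

test_that("clamping stays rare on clean raised-cosine traces", {
  fr <- vapply(1:5, function(s) {
    d <- synth_decomp(synth_config(duration_s = 120, noise_sd_mm = 0.3,
                                   shape_exponent = 1, seed = 30 + s))
    mean(d$dec$clamped[d$dec$valid])
  }, numeric(1))
  expect_true(all(fr < 0.01))
})

test_that("reassembly evaluates the modulated-cosine model exactly", {
  expect_equal(reassemble_signal(0, 3, 1), 7)
  expect_equal(reassemble_signal(180, 3, 1), 1)
  expect_equal(reassemble_signal(90, 2.5, -0.5), 2.0)
  expect_error(reassemble_signal(0, -1, 0), class = "bc_invalid_components")
})

test_that("degenerate envelope and insufficient anchors are reported", {
  sig <- cosine_signal(12)
  pk <- detect_peaks(sig)
  pk$upper_idx <- pk$upper_idx[1]
  pk$anchors <- pk$anchors[pk$anchors$idx %in% c(pk$upper_idx, pk$lower_idx), ]
  # still >= 1 of each: envelopes constructible (single-node upper curve)
  env <- build_envelopes(sig, pk)
  expect_s3_class(env, "tbl_df")

  pk$anchors <- pk$anchors[1, ]
  pk$lower_idx <- integer(0)
  expect_error(build_envelopes(sig, pk), class = "bc_insufficient_peaks")
})
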