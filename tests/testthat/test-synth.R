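test_that("generation is bit-reproducible under its seed", {
  cfg <- synth_config(duration_s = 60, noise_sd_mm = 0.3, seed = 42)
  a <- generate_trace(cfg)
  b <- generate_trace(cfg)
  expect_identical(a$signal$pos_mm, b$signal$pos_mm)
  expect_identical(a$truth, b$truth)
  c <- generate_trace(synth_config(duration_s = 60, noise_sd_mm = 0.3,
                                   seed = 43))
  expect_false(identical(a$signal$pos_mm, c$signal$pos_mm))
})

test_that("a noiseless constant-parameter configuration is an exact raised cosine", {
  cfg <- synth_config(duration_s = 60, period_sd_s = 0, amplitude_sd_mm = 0,
                      amplitude_drift_frac = 0, baseline_drift_mm = 0,
                      noise_sd_mm = 0, shape_exponent = 1, seed = 1)
  tr <- generate_trace(cfg)
  t <- tr$signal$time_s
  want <- 10.7 / 2 * (1 + cospi(2 * t / 4))
  expect_lt(max(abs(tr$signal$pos_mm - want)), 1e-9)
})

test_that("decomposition recovers the generator's ground truth on clean traces", {
  # slow envelope modulation relative to cycle curvature keeps the sampled
  # extrema on the analytic anchors, so recovery is exact to rounding
  cfg <- synth_config(duration_s = 120, amplitude_sd_mm = 0.25,
                      amplitude_drift_frac = 0.05, baseline_drift_mm = 1.0,
                      noise_sd_mm = 0, shape_exponent = 1, seed = 7)
  tr <- generate_trace(cfg)
  out <- list(trace = tr,
              dec = suppressWarnings(decompose_signal(tr$signal)))
  both <- out$dec$valid & out$trace$truth$valid
  expect_gt(sum(both), 1500)
  expect_lt(max(abs(out$dec$deflection_mm[both] -
                      out$trace$truth$deflection_mm[both])), 1e-6)
  expect_lt(max(abs(out$dec$baseline_mm[both] -
                      out$trace$truth$baseline_mm[both])), 1e-6)
  expect_lt(max(abs(out$dec$phase_unwrapped_deg[both] -
                      out$trace$truth$phase_unwrapped_deg[both])), 0.5)
})

test_that("recovery error grows monotonically with the noise level", {
  err_at <- function(noise) {
    median(vapply(1:4, function(s) {
      out <- synth_decomp(synth_config(duration_s = 90, noise_sd_mm = noise,
                                       amplitude_sd_mm = 0.25,
                                       amplitude_drift_frac = 0.05,
                                       baseline_drift_mm = 1.0,
                                       seed = 100 + s))
      both <- out$dec$valid & out$trace$truth$valid
      sqrt(mean((out$dec$deflection_mm[both] -
                   out$trace$truth$deflection_mm[both])^2))
    }, numeric(1)))
  }
  errs <- vapply(c(0, 0.2, 0.6, 1.5), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("empirical cycle statistics converge to the configured means", {
  cfg <- synth_config(duration_s = 600, amplitude_mean_mm = 10.7,
                      amplitude_sd_mm = 1.0, amplitude_drift_frac = 0.05,
                      noise_sd_mm = 0, seed = 77)
  tr <- generate_trace(cfg)
  # oracle: the drawn per-cycle amplitudes themselves
  expect_lt(abs(mean(tr$cycles$amplitude_mm) - 10.7) / 10.7, 0.05)
  expect_lt(abs(mean(tr$cycles$period_s) - 4) / 4, 0.05)
  # and the trace realises them: detected swings match the drawn amplitudes
  dec <- suppressWarnings(decompose_signal(lowpass_signal(tr$signal)))
  swings <- abs(diff(decomp_peaks(dec)$anchors$pos_mm))
  expect_lt(abs(mean(swings) - mean(tr$cycles$amplitude_mm)) /
              mean(tr$cycles$amplitude_mm), 0.05)
})

test_that("cohort generation produces a manifest consistent with its traces", {
  coh <- generate_cohort(4, sites = c("sternum", "abdomen"), duration_s = 45,
                         noise_sd_mm = 0.2, seed = 3)
  expect_length(coh$traces, 8)
  expect_equal(nrow(coh$manifest), 8)
  expect_equal(sum(coh$manifest$site == "abdomen"), 4)
  expect_equal(length(unique(coh$manifest$subject)), 4)
  # reproducible from the master seed
  coh2 <- generate_cohort(4, sites = c("sternum", "abdomen"), duration_s = 45,
                          noise_sd_mm = 0.2, seed = 3)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$traces[[5]]$signal$pos_mm,
                   coh2$traces[[5]]$signal$pos_mm)
  # abdomen preset reaches 'large'-eligible cycle amplitudes
  abd <- which(coh$manifest$site == "abdomen")
  amps <- unlist(lapply(coh$traces[abd],
                        function(tr) tr$cycles$amplitude_mm))
  expect_true(any(amps > 12))
  # site presets separate as intended: abdomen much deeper than sternum
  stern <- which(coh$manifest$site == "sternum")
  expect_gt(mean(coh$manifest$amplitude_mean_mm[abd]),
            2 * mean(coh$manifest$amplitude_mean_mm[stern]))
})

test_that("configuration validation rejects impossible parameters", {
  expect_error(synth_config(period_mean_s = -1), class = "bc_invalid_config")
  expect_error(synth_config(shape_exponent = 0.5),
               class = "bc_invalid_config")
  expect_error(synth_config(duration_s = 5), class = "bc_invalid_config")
  expect_error(generate_cohort(0), class = "bc_invalid_config")
  expect_error(generate_cohort(2, sites = "thorax"),
               class = "bc_invalid_config")
})
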