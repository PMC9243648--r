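test_that("noiseless zero-drop channels are pure sinusoids", {
  sc <- fast_scenario(drop_590 = 0, drop_780 = 0, noise_sd = 0)
  rec <- generate_recording(sc)
  n <- length(rec$channel_590)
  t <- (seq_len(n) - 1) / rec$sample_rate
  expect_equal(rec$channel_590, sin(2 * pi * 1100 * t))
  expect_equal(rec$channel_780, sin(2 * pi * 1000 * t))
  expect_equal(rec$true_envelopes$e_590, rep(1, n))
})

test_that("recordings are deterministic per seed", {
  a <- generate_recording(fast_scenario(seed = 9))
  b <- generate_recording(fast_scenario(seed = 9))
  expect_identical(a$channel_590, b$channel_590)
  expect_identical(a$channel_780, b$channel_780)
  c2 <- generate_recording(fast_scenario(seed = 10))
  expect_false(identical(a$channel_590, c2$channel_590))
})

test_that("end-of-occlusion envelopes match the configured drops", {
  sc <- fast_scenario(noise_sd = 0)
  rec <- generate_recording(sc)
  fs <- rec$sample_rate
  i_end <- round(fs * (sc$baseline_duration + sc$occlusion_duration))
  expect_equal(rec$true_envelopes$e_590[i_end], 0.75, tolerance = 1e-3)
  expect_equal(rec$true_envelopes$e_780[i_end], 0.97, tolerance = 1e-3)
})

test_that("lock-in recovers amplitudes with negligible cross-talk", {
  sc <- fast_scenario(drop_590 = 0, drop_780 = 0, noise_sd = 0,
                      amplitude_590 = 0.5, amplitude_780 = 0.3)
  rec <- generate_recording(sc)
  d <- lock_in_demodulate(rec)
  expect_equal(attr(d, "rate"), 50)
  expect_true(all(abs(d$ve_590 - 0.5) < 0.5 * 1e-3))
  expect_true(all(abs(d$ve_780 - 0.3) < 0.3 * 1e-3))

  # cross-talk: demodulate a two-tone mixture at each carrier separately
  mix <- 0.5 * rec$channel_590 / 0.5 + 0  # unit 1100 Hz tone
  rec2 <- rec
  rec2$channel_590 <- rec$channel_590 + rec$channel_780  # both tones
  d2 <- lock_in_demodulate(rec2)
  # the 1000 Hz component must not leak into the 1100 Hz estimate
  expect_true(all(abs(d2$ve_590 - 0.5) < 1e-6))
})

test_that("demodulation recovers generated envelopes within noise", {
  sc <- fast_scenario(noise_sd = 0.01, seed = 3)
  rec <- generate_recording(sc)
  d <- lock_in_demodulate(rec)
  w <- rec$sample_rate / 50
  env_w <- colMeans(matrix(rec$true_envelopes$e_590, nrow = w))
  rel_rmse <- sqrt(mean((d$ve_590 - env_w)^2)) / mean(env_w)
  expect_lt(rel_rmse, 2 * sc$noise_sd / sqrt(w))
})

test_that("window validation enforces integer carrier cycles", {
  rec <- generate_recording(fast_scenario(noise_sd = 0))
  expect_error(lock_in_demodulate(rec, window_length = 250), "integer")
  expect_error(lock_in_demodulate(rec, window_length = 333), "divide")
  expect_error(occlusion_scenario(sample_rate = 12345), "integer")
  expect_error(occlusion_scenario(drop_590 = 1.2), "drops")
  expect_error(occlusion_scenario(baseline_duration = -1), "positive")
})

test_that("phase labels follow the protocol timeline", {
  d <- lock_in_demodulate(generate_recording(fast_scenario(noise_sd = 0)))
  expect_equal(attr(d, "occlusion_start"), 20)
  expect_equal(attr(d, "release_start"), 100)
  expect_setequal(unique(d$phase), c("baseline", "occlusion", "release"))
  expect_true(all(d$phase[d$time < 20] == "baseline"))
  expect_true(all(d$phase[d$time > 100] == "release"))
})
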