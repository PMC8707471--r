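test_that("ECG generator produces the requested rhythm and morphology", {
  expect_length(gen_ecg(ecg_profile(), 0, fs = 500), 0)

  ecg <- gen_ecg(ecg_profile(hr_bpm = 60), 10, fs = 500, seed = 1)
  expect_lte(abs(peak_count_oracle(ecg$samples) - 10), 1)

  # distinct class templates: one noiseless beat each, lag-aligned
  tpl <- lapply(c("normal", "hypotension", "hypertension"), function(cl) {
    p <- ecg_profile(cl, hr_bpm = 60, rr_jitter = 0)
    gen_ecg(p, 2, fs = 500, seed = 1)$samples
  })
  for (i in 1:2) for (j in (i + 1):3) {
    cc <- stats::ccf(tpl[[i]], tpl[[j]], lag.max = 250, plot = FALSE)$acf
    expect_lt(max(cc), 0.999)
  }

  expect_error(gen_ecg(ecg_profile(), 1, fs = 100), "fs")
  expect_error(ecg_profile(hr_bpm = -10), "positive")
})

test_that("EEG generator matches its state labels and physiological bounds", {
  fs <- 250
  drowsy <- gen_eeg(eeg_state_spec("drowsy"), 8, fs, seed = 3)
  a <- bandvar_oracle(drowsy, 8, 12)
  b <- bandvar_oracle(drowsy, 14, 25)
  expect_gt(a, b)

  zero <- gen_eeg(eeg_state_spec("eyes_open", alpha_amp = 0, beta_amp = 0,
                                 broadband_noise_amp = 0), 2, fs, seed = 1)
  expect_true(all(zero$samples == 0))

  closed <- gen_eeg(eeg_state_spec("eyes_closed_relaxed", alpha_amp = 40),
                    30, 1000, seed = 1)
  alpha_only <- apply_filter(closed, filter_spec("bandpass", f_lo = 8,
                                                 f_hi = 12))
  expect_lte(max(abs(alpha_only$samples)), 150)

  expect_error(eeg_state_spec("drowsy", alpha_amp = 200), "5-150")
  expect_error(eeg_state_spec("drowsy", alpha_amp = 2), "5-150")
})

test_that("EEG state specs order alpha vs beta power as documented", {
  # label/signal consistency across every state, via the band-limited
  # variance oracle
  expected_alpha_dominant <- c(eyes_open = FALSE, eyes_closed_relaxed = TRUE,
                               drowsy = TRUE, stress = FALSE, emotion = FALSE,
                               distraction = FALSE)
  for (st in names(expected_alpha_dominant)) {
    tr <- gen_eeg(eeg_state_spec(st), 8, 250, seed = 11)
    a <- bandvar_oracle(tr, 8, 12)
    b <- bandvar_oracle(tr, 14, 25)
    if (expected_alpha_dominant[[st]]) expect_gt(a, b) else expect_lt(a, b)
  }
})

test_that("generators are bit-identical under identical seeds", {
  e1 <- gen_ecg(ecg_profile(), 5, 500, seed = 42)
  e2 <- gen_ecg(ecg_profile(), 5, 500, seed = 42)
  expect_identical(e1$samples, e2$samples)

  g1 <- gen_eeg(eeg_state_spec("stress"), 4, 250, seed = 42)
  g2 <- gen_eeg(eeg_state_spec("stress"), 4, 250, seed = 42)
  expect_identical(g1$samples, g2$samples)

  p1 <- gen_ppg_pair(95, duration_s = 5, fs = 250, seed = 42, noise_sd = 0.01)
  p2 <- gen_ppg_pair(95, duration_s = 5, fs = 250, seed = 42, noise_sd = 0.01)
  expect_identical(p1$red$samples, p2$red$samples)

  t1 <- gen_thermal_sequence("flame", 20, seed = 42)
  t2 <- gen_thermal_sequence("flame", 20, seed = 42)
  expect_identical(t1[[20]]$temps, t2[[20]]$temps)
})

test_that("PPG pairs invert the oximetry calibration", {
  for (s in c(85, 90, 95, 98)) {
    p <- gen_ppg_pair(s, duration_s = 10, fs = 250, seed = 2)
    expect_lte(abs(estimate_spo2(p)$spo2 - s), 1)
  }
  # lower saturation -> strictly larger ratio of ratios
  r85 <- ratio_R(extract_ac_dc(gen_ppg_pair(85, duration_s = 10, fs = 250,
                                            seed = 2)))
  r98 <- ratio_R(extract_ac_dc(gen_ppg_pair(98, duration_s = 10, fs = 250,
                                            seed = 2)))
  expect_gt(r85, r98)
  expect_error(gen_ppg_pair(50), "70-100")
})

test_that("thermal sequences realise their regimes on an 8x8 grid", {
  amb <- gen_thermal_sequence("ambient", 50, fps = 10, seed = 5)
  expect_true(all(vapply(amb, function(f) length(f$temps) == 64L, logical(1))))
  # per-pixel slopes consistent with zero within pixel noise: 4 standard
  # errors of a least-squares slope under sigma = 0.3 degC
  tt <- (0:49) / 10
  slope_sd <- 0.3 / sqrt(sum((tt - mean(tt))^2))
  expect_lt(max(abs(temporal_gradient(amb))), 4 * slope_sd)

  fl <- gen_thermal_sequence("flame", 50, fps = 10, seed = 5)
  expect_gt(max(vapply(fl, function(f) max(f$temps), numeric(1))), 80)

  expect_error(gen_thermal_sequence("volcano"), "arg")
  expect_error(gen_thermal_sequence("ambient", 0), ">= 1")
})

test_that("capacitive channel: identity, divider gain, hum and linearity", {
  tr <- signal_trace(sin(2 * pi * 10 * (0:499) / 500), fs = 500)
  ident <- capacitive_channel(layers = list())
  expect_identical(apply_capacitive_channel(tr, ident)$samples, tr$samples)

  # single layer L = 0, C = 10 nF against Z_in: hand-computed divider
  # magnitude at 10 Hz (tone on an exact FFT bin)
  C <- 10e-9; z_in <- 1e8
  ch <- capacitive_channel(layers = list(c(L = 0, C = C)), z_in = z_in)
  out <- apply_capacitive_channel(tr, ch)
  zc <- 1 / (2 * pi * 10 * C)
  gain_hand <- z_in / sqrt(z_in^2 + zc^2)
  gain_meas <- sqrt(mean(out$samples^2)) / sqrt(mean(tr$samples^2))
  expect_equal(gain_meas, gain_hand, tolerance = 1e-6)

  # mains hum shows as a 50 Hz spectral peak
  quiet <- signal_trace(rnorm(4096, sd = 0.01), fs = 500)
  hum <- apply_capacitive_channel(quiet,
    capacitive_channel(layers = list(), mains_amp = 1, seed = 7))
  psd <- welch_psd(hum, welch_spec(M = 1024, fs = 500))
  i50 <- which.min(abs(psd$freqs - 50))
  expect_true(psd$power[i50] > psd$power[i50 - 2] &&
                psd$power[i50] > psd$power[i50 + 2])
  expect_equal(which.max(psd$power), i50)

  # linearity in the input when all noise is off
  ch2 <- capacitive_channel(layers = list(c(0, 10e-9), c(1e-3, 47e-9)))
  x1 <- signal_trace(rnorm(256), fs = 500)
  x2 <- signal_trace(rnorm(256), fs = 500)
  lhs <- apply_capacitive_channel(
    signal_trace(2 * x1$samples + 3 * x2$samples, fs = 500), ch2)$samples
  rhs <- 2 * apply_capacitive_channel(x1, ch2)$samples +
    3 * apply_capacitive_channel(x2, ch2)$samples
  expect_equal(lhs, rhs, tolerance = 1e-10)

  expect_error(capacitive_channel(layers = list(c(0, -1))), "capacitance")
})
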