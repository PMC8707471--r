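test_that("segmentation combinatorics follow K = floor((N-M)/D) + 1", {
  expect_length(segment_signal(1:8, M = 4, D = 4), 2)
  s <- segment_signal(1:8, M = 4, D = 2)
  expect_length(s, 3)
  expect_equal(s[[2]], 3:6)
  expect_equal(segment_signal(1:4, M = 4, D = 1), list(1:4))
  expect_error(segment_signal(1:4, M = 5, D = 1), "exceed")
})

test_that("modified periodogram matches its direct-summation definition", {
  fs <- 32
  # rectangular window equals the plain periodogram
  set.seed(3)
  x <- rnorm(16)
  p <- modified_periodogram(x, "rectangular", fs)
  plain <- Mod(fft(x)[1:9])^2 / (fs * 16) * c(1, rep(2, 7), 1)
  expect_equal(p$power, plain, tolerance = 1e-12)

  # direct-sum reference on a random segment, Hann taper
  w <- hann_oracle(16)
  p2 <- modified_periodogram(x, w, fs)
  ref <- welch_direct_oracle(x, M = 16, D = 16, w = w, fs = fs)
  expect_equal(p2$power, ref$power, tolerance = 1e-10)

  # unit sinusoid on a bin centre: peak bin and one-sided power ~ 0.5
  fs <- 64; M <- 64
  tone <- sin(2 * pi * 8 * (0:(M - 1)) / fs)
  for (win in list("rectangular", hann_oracle(M))) {
    pt <- modified_periodogram(tone, win, fs)
    expect_equal(pt$freqs[which.max(pt$power)], 8)
    total <- sum(pt$power) * fs / M
    expect_equal(total, 0.5, tolerance = 0.02)
  }
  expect_error(modified_periodogram(tone, rep(0, M), fs), "zero-energy")
})

test_that("Welch estimator agrees with the literal transcription", {
  set.seed(9)
  fs <- 32
  for (N in c(24, 48, 64)) {
    x <- rnorm(N)
    for (MD in list(c(8, 8), c(8, 4), c(16, 8), c(12, 3))) {
      M <- MD[1]; D <- MD[2]
      w <- hann_oracle(M)
      est <- welch_psd(signal_trace(x, fs = fs),
                       welch_spec(M = M, D = D, window = "hann", fs = fs))
      ref <- welch_direct_oracle(x, M, D, w, fs)
      expect_equal(est$power, ref$power, tolerance = 1e-10)
      expect_equal(est$freqs, ref$freqs, tolerance = 1e-12)
    }
  }
})

test_that("Welch estimator is scale-equivariant and integrates to the variance", {
  set.seed(21)
  x <- signal_trace(rnorm(2048), fs = 128)
  spec <- welch_spec(M = 256, fs = 128)
  p1 <- welch_psd(x, spec)
  p3 <- welch_psd(signal_trace(3 * x$samples, fs = 128), spec)
  expect_equal(p3$power, 9 * p1$power, tolerance = 1e-12)

  # overlap consistency on a stationary tone
  t <- (0:2047) / 128
  tone <- signal_trace(sin(2 * pi * 16 * t), fs = 128)
  pa <- welch_psd(tone, welch_spec(M = 256, D = 256, fs = 128))
  pb <- welch_psd(tone, welch_spec(M = 256, D = 128, fs = 128))
  expect_equal(band_power(pa, 14, 18), band_power(pb, 14, 18),
               tolerance = 0.05)

  # DC: constant signal puts all power in the zero bin
  pc <- welch_psd(signal_trace(rep(2, 512), fs = 128),
                  welch_spec(M = 128, window = "rectangular", fs = 128))
  expect_equal(which.max(pc$power), 1L)
  expect_lt(sum(pc$power[-1]), 1e-20 * pc$power[1])

  # Parseval over seeded white-noise trials
  err <- vapply(1:100, function(s) {
    set.seed(s)
    v <- rnorm(4096, sd = 1.5)
    tr <- signal_trace(v, fs = 256)
    psd <- welch_psd(tr, welch_spec(M = 512, fs = 256))
    abs(band_power(psd, 0, 128) - var(v)) / var(v)
  }, numeric(1))
  expect_lt(mean(err), 0.10)
  expect_lt(max(err), 0.25)
})

test_that("band power integrates the PSD correctly", {
  fs <- 128
  t <- (0:4095) / fs
  tone <- signal_trace(sin(2 * pi * 10 * t), fs = fs)
  psd <- welch_psd(tone, welch_spec(M = 512, fs = fs))
  total <- band_power(psd, 0, fs / 2)
  expect_gt(band_power(psd, 8, 12) / total, 0.90)

  # additivity over a partition of [0, fs/2]
  parts <- band_power(psd, 0, 20) + band_power(psd, 20, 40) +
    band_power(psd, 40, fs / 2)
  expect_equal(parts, total, tolerance = 1e-10)

  # band with no signal support
  expect_lt(band_power(psd, 50, 60), 1e-4 * total)
  expect_error(band_power(psd, 12, 8), "f_lo")
})

test_that("drowsiness scoring flags alpha dominance against a baseline", {
  fs <- 250
  baseline <- eeg_band_power(gen_eeg(eeg_state_spec("eyes_open"), 8, fs,
                                     seed = 1))
  drowsy_ep <- gen_eeg(eeg_state_spec("drowsy"), 8, fs, seed = 2)
  sc <- drowsiness_score(drowsy_ep, baseline, threshold_mult = 1.5)
  expect_true(sc$drowsy)

  # an epoch scored against its own band powers is never drowsy for
  # threshold_mult > 1
  self_ep <- gen_eeg(eeg_state_spec("eyes_open"), 8, fs, seed = 3)
  self_bp <- eeg_band_power(self_ep)
  expect_false(drowsiness_score(self_ep, self_bp, 1.1)$drowsy)
  expect_false(drowsiness_score(self_ep, self_bp, 3)$drowsy)

  # monotone in the generator's alpha amplitude
  ratios <- vapply(c(10, 25, 60, 120), function(a) {
    ep <- gen_eeg(eeg_state_spec("drowsy", alpha_amp = a, beta_amp = 10,
                                 broadband_noise_amp = 2), 8, fs, seed = 4)
    drowsiness_score(ep, baseline)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))

  # vanishing beta power: indeterminate, not an error
  pure_alpha <- gen_eeg(eeg_state_spec("drowsy", alpha_amp = 40,
                                       beta_amp = 0,
                                       broadband_noise_amp = 0), 8, fs,
                        seed = 5)
  zb <- eeg_band_power(pure_alpha)
  sc2 <- drowsiness_score(pure_alpha, structure(list(
    alpha_power = zb$alpha_power, beta_power = 0,
    alpha_band = c(8, 12), beta_band = c(14, 25)),
    class = "band_power_pair"))
  expect_true(sc2$indeterminate)
  expect_true(is.na(sc2$drowsy))
})
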