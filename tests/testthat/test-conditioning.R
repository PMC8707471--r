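test_that("notch and band-pass filters behave on tones", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  tone50 <- signal_trace(sin(2 * pi * 50 * t), fs = fs)
  out <- apply_filter(tone50, filter_spec("notch", f0 = 50))
  # evaluate away from the filtfilt edge transients
  core <- seq(fs, 3 * fs)
  expect_lt(sqrt(mean(out$samples[core]^2)), 0.01 * sqrt(mean(tone50$samples[core]^2)))

  tone10 <- signal_trace(sin(2 * pi * 10 * t), fs = fs)
  bp <- apply_filter(tone10, filter_spec("bandpass", f_lo = 0.5, f_hi = 35))
  gain <- sqrt(mean(bp$samples[core]^2) / mean(tone10$samples[core]^2))
  expect_lt(abs(gain - 1), 0.05)

  zero <- signal_trace(numeric(1000), fs = fs)
  expect_true(all(apply_filter(zero, filter_spec("notch", f0 = 50))$samples == 0))
  expect_true(all(apply_filter(zero,
    filter_spec("moving_average", window_len = 5))$samples == 0))

  expect_error(apply_filter(tone10, filter_spec("bandpass", f_lo = 1,
                                                f_hi = 300)), "fs/2")
})

test_that("zero-phase filtering leaves in-band tones unshifted", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  tone <- signal_trace(sin(2 * pi * 10 * t), fs = fs)
  out <- apply_filter(tone, filter_spec("bandpass", f_lo = 0.5, f_hi = 35))
  core <- seq(fs, 3 * fs)
  cc <- stats::ccf(out$samples[core], tone$samples[core], lag.max = 25,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("dyadic Haar coefficients equal brute-force basis inner products", {
  # constant signal: no detail
  const <- signal_trace(rep(1, 4), fs = 10)
  co <- dwt_coeffs(const, wavelet_spec(levels = 1))
  expect_equal(co$details[[1]], c(0, 0))

  set.seed(7)
  x <- rnorm(8)
  tr <- signal_trace(x, fs = 10)
  co <- dwt_coeffs(tr, wavelet_spec(levels = 3))
  B <- haar_basis(8, 3)
  ref <- as.numeric(B %*% x)
  # basis row order: scaling, then details coarse (j=3) to fine (j=1)
  got <- c(co$approx, co$details[[3]], co$details[[2]], co$details[[1]])
  expect_equal(got, ref, tolerance = 1e-10)

  # orthonormality of the explicit family
  G <- B %*% t(B)
  expect_equal(G, diag(8), tolerance = 1e-12)

  # Parseval: coefficient energy equals signal energy
  expect_equal(sum(got^2), sum(x^2), tolerance = 1e-10)

  expect_error(dwt_coeffs(signal_trace(rnorm(6), fs = 10),
                          wavelet_spec(levels = 3)), "multiple")
})

test_that("stationary Haar denoising reconstructs, denoises and commutes with shifts", {
  set.seed(11)
  tr <- signal_trace(rnorm(512), fs = 500)
  zero_thr <- wavelet_spec(threshold_rule = "fixed", threshold_values = 0)
  expect_equal(swt_denoise(tr, zero_thr)$samples, tr$samples,
               tolerance = 1e-8)

  # non-dyadic length: padding round-trips too
  tr2 <- signal_trace(rnorm(500), fs = 500)
  expect_equal(swt_denoise(tr2, zero_thr)$samples, tr2$samples,
               tolerance = 1e-8)

  clean <- gen_ecg(ecg_profile(hr_bpm = 75), 10, fs = 500, seed = 5)
  noisy <- trace_with_noise(clean, snr_db = 5, seed = 6)
  den <- swt_denoise(noisy, wavelet_spec())
  expect_lt(rmse(den$samples, clean$samples),
            rmse(noisy$samples, clean$samples))

  # shift equivariance under circular shifts (dyadic length)
  spec <- wavelet_spec(threshold_rule = "fixed", threshold_values = 0.8)
  x <- rnorm(256)
  for (k in c(1, 7, 100)) {
    xs <- c(x[-(1:k)], x[1:k])
    a <- swt_denoise(signal_trace(xs, fs = 500), spec)$samples
    b <- swt_denoise(signal_trace(x, fs = 500), spec)$samples
    expect_equal(a, c(b[-(1:k)], b[1:k]), tolerance = 1e-10)
  }

  # threshold -> infinity on zero-mean noise: only the coarse trend remains
  noise <- signal_trace(rnorm(512), fs = 500)
  flat <- swt_denoise(noise, wavelet_spec(threshold_rule = "fixed",
                                          threshold_values = 1e9))
  expect_lt(stats::sd(flat$samples), 0.5 * stats::sd(noise$samples))

  expect_error(wavelet_spec(family = "db4"), "family")
})
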