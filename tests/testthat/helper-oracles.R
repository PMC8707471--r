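# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations: band-limited variance goes through direct
# FFT masking, the Welch reference is a literal direct-summation
# transcription of the averaged-modified-periodogram definition, and peak
# counting is brute-force local-maxima enumeration.

# Variance of the band-limited component of a trace, by FFT masking.
bandvar_oracle <- function(trace, f_lo, f_hi) {
  x <- trace$samples
  n <- length(x)
  f <- (seq_len(n) - 1) * trace$fs / n
  f <- pmin(f, trace$fs - f)  # two-sided frequency magnitude
  X <- fft(x)
  X[!(f >= f_lo & f <= f_hi)] <- 0
  xb <- Re(fft(X, inverse = TRUE)) / n
  mean(xb^2)
}

# Brute-force count of prominent local maxima (above frac * global max).
peak_count_oracle <- function(x, frac = 0.5) {
  n <- length(x)
  thr <- frac * max(x)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1
  sum(x[idx] > thr)
}

# Literal direct-summation Welch reference: segments x[n + iD], taper w,
# modified periodogram |sum_n x_i[n] w[n] e^(-j 2 pi n f)|^2 / (M U) with
# U = mean(w^2), averaged over segments, then scaled to a one-sided
# density on the grid f = k / M cycles/sample (divide by fs; double all
# bins except DC and, for even M, Nyquist).
welch_direct_oracle <- function(x, M, D, w, fs) {
  N <- length(x)
  K <- floor((N - M) / D) + 1
  U <- sum(w^2) / M
  n_keep <- floor(M / 2) + 1
  acc <- numeric(n_keep)
  for (i in 0:(K - 1)) {
    xi <- x[(i * D + 1):(i * D + M)]
    for (k in 0:(n_keep - 1)) {
      f <- k / M
      s <- sum(xi * w * exp(-2i * pi * (0:(M - 1)) * f))
      acc[k + 1] <- acc[k + 1] + Mod(s)^2 / (M * U)
    }
  }
  p <- acc / K / fs
  scale <- rep(2, n_keep)
  scale[1] <- 1
  if (M %% 2 == 0) scale[n_keep] <- 1
  list(freqs = (0:(n_keep - 1)) * fs / M, power = p * scale)
}

# Hann taper matching the estimator's periodic convention.
hann_oracle <- function(M) 0.5 * (1 - cos(2 * pi * (0:(M - 1)) / M))

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Split an epoch dataset per class into train/test parts.
split_dataset <- function(ds, n_train_per_class) {
  idx <- unlist(lapply(levels(ds$labels), function(lv) {
    which(ds$labels == lv)[seq_len(n_train_per_class)]
  }))
  train <- structure(list(epochs = ds$epochs[idx], labels = ds$labels[idx]),
                     class = "epoch_dataset")
  test <- structure(list(epochs = ds$epochs[-idx], labels = ds$labels[-idx]),
                    class = "epoch_dataset")
  list(train = train, test = test)
}
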