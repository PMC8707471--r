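#' Welch estimator specification
#'
#' Segment length `M`, hop `D` and taper for the averaged-modified-
#' periodogram spectral estimator. With `D = M` the segments are disjoint;
#' `D = M/2` gives the recommended 50 percent overlap. The default for EEG
#' work is an 8-second Hann-tapered segment with 50 percent overlap.
#'
#' @param M segment length in samples.
#' @param D hop size in samples, `1 <= D <= M`.
#' @param window `"hann"` or `"rectangular"`, or a numeric vector of
#'   length `M` giving the taper directly.
#' @param fs sampling rate in Hz.
#' @return An object of class `welch_spec`.
#' @export
welch_spec <- function(M, D = max(1L, floor(M / 2)), window = "hann", fs) {
  M <- as.integer(M); D <- as.integer(D)
  if (M < 1 || D < 1 || D > M) stop("need 1 <= D <= M", call. = FALSE)
  if (missing(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  structure(list(M = M, D = D, window = window, fs = fs),
            class = "welch_spec")
}

# Resolve the taper vector for a spec. Hann here is the periodic taper
# 0.5 * (1 - cos(2*pi*n/M)), n = 0..M-1.
welch_window <- function(spec) {
  if (is.numeric(spec$window)) {
    w <- as.numeric(spec$window)
    if (length(w) != spec$M) stop("window length must equal M", call. = FALSE)
    return(w)
  }
  switch(match.arg(spec$window, c("hann", "rectangular")),
    hann = 0.5 * (1 - cos(2 * pi * (seq_len(spec$M) - 1) / spec$M)),
    rectangular = rep(1, spec$M)
  )
}

#' Split a sample vector into (possibly overlapping) segments
#'
#' Segment `i` (0-based) is `x[iD + 1 .. iD + M]`; the number of segments
#' is `K = floor((N - M) / D) + 1`. A trailing remainder shorter than `M`
#' is dropped.
#'
#' @param x numeric sample vector.
#' @param M segment length in samples (`M <= length(x)`).
#' @param D hop size in samples.
#' @return A list of `K` numeric vectors, each of length `M`.
#' @examples
#' segment_signal(1:8, M = 4, D = 2)  # 3 segments, 50% overlap
#' @export
segment_signal <- function(x, M, D) {
  N <- length(x)
  if (M > N) stop("`M` must not exceed the signal length", call. = FALSE)
  if (D < 1 || D > M) stop("need 1 <= D <= M", call. = FALSE)
  K <- floor((N - M) / D) + 1
  lapply(seq_len(K) - 1, function(i) x[(i * D + 1):(i * D + M)])
}

#' Modified periodogram of a single segment
#'
#' Tapers the segment, takes the squared magnitude of its DFT and
#' normalizes by the segment length and the window power factor
#' `U = mean(w^2)`, then scales to a one-sided power spectral density:
#' `P(f_k) = c_k * |DFT(x * w)[k]|^2 / (fs * M * U)` with `c_k = 2` except
#' at DC and (for even `M`) Nyquist, where `c_k = 1`. Integrating the
#' density over `[0, fs/2]` recovers the segment's mean power.
#'
#' @param segment numeric vector of samples.
#' @param window taper vector of the same length (or name as in
#'   [welch_spec()]).
#' @param fs sampling rate in Hz.
#' @return An object of class `psd_estimate`: list with `freqs` (Hz,
#'   `0 .. fs/2`) and `power` (density, units^2/Hz).
#' @export
modified_periodogram <- function(segment, window, fs) {
  M <- length(segment)
  if (M < 1) stop("empty segment", call. = FALSE)
  if (is.character(window)) {
    window <- welch_window(welch_spec(M, M, window, fs))
  }
  if (length(window) != M) {
    stop("window length must equal the segment length", call. = FALSE)
  }
  U <- mean(window^2)
  if (U <= 0) stop("zero-energy window", call. = FALSE)
  X <- stats::fft(segment * window)
  n_keep <- floor(M / 2) + 1
  p <- Mod(X[seq_len(n_keep)])^2 / (fs * M * U)
  scale <- rep(2, n_keep)
  scale[1] <- 1
  if (M %% 2 == 0) scale[n_keep] <- 1
  structure(list(freqs = (seq_len(n_keep) - 1) * fs / M, power = p * scale,
                 spec = NULL),
            class = "psd_estimate")
}

#' Welch power spectral density
#'
#' Averaged-modified-periodogram estimator: the signal is segmented with
#' hop `D`, each segment is tapered and its modified periodogram computed,
#' and the estimate is the arithmetic mean of the per-segment periodograms.
#' Overlap (`D < M`) reduces the variance of the estimate relative to
#' disjoint segmentation at the same record length.
#'
#' @param trace a [signal_trace()] (its `fs` overrides `spec$fs` if they
#'   disagree).
#' @param spec a [welch_spec()].
#' @return A `psd_estimate` with `freqs` (Hz), `power` (density) and the
#'   spec used.
#' @examples
#' tr <- signal_trace(rnorm(2048), fs = 256)
#' psd <- welch_psd(tr, welch_spec(M = 256, fs = 256))
#' @export
welch_psd <- function(trace, spec) {
  stopifnot(inherits(trace, "signal_trace"), inherits(spec, "welch_spec"))
  fs <- trace$fs
  w <- welch_window(spec)
  segs <- segment_signal(trace$samples, spec$M, spec$D)
  acc <- NULL
  for (s in segs) {
    p <- modified_periodogram(s, w, fs)
    acc <- if (is.null(acc)) p$power else acc + p$power
  }
  structure(list(freqs = (seq_len(floor(spec$M / 2) + 1) - 1) * fs / spec$M,
                 power = acc / length(segs), spec = spec),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0-%.4g Hz, total power %.4g\n",
              length(x$freqs), max(x$freqs),
              band_power(x, 0, max(x$freqs))))
  invisible(x)
}

#' Band power from a PSD estimate
#'
#' Trapezoidal integral of the power spectral density over a frequency
#' band, with linear interpolation at the band edges when they fall
#' between grid points.
#'
#' @param psd a `psd_estimate`.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= max(freqs)`.
#' @return Scalar band power (signal units squared).
#' @export
band_power <- function(psd, f_lo, f_hi) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (f_lo < 0 || f_hi <= f_lo) stop("need 0 <= f_lo < f_hi", call. = FALSE)
  f <- psd$freqs; p <- psd$power
  f_hi <- min(f_hi, max(f))
  if (f_lo >= max(f)) return(0)
  # close the band with interpolated edge points
  inside <- f > f_lo & f < f_hi
  fk <- c(f_lo, f[inside], f_hi)
  pk <- c(stats::approx(f, p, f_lo)$y, p[inside],
          stats::approx(f, p, f_hi)$y)
  sum(diff(fk) * (utils::head(pk, -1) + utils::tail(pk, -1)) / 2)
}

#' Alpha/beta band powers of an EEG epoch
#'
#' Welch band powers in the alpha (8-12 Hz) and beta (14-25 Hz) bands,
#' the two features driving drowsiness scoring: alpha rises and beta falls
#' as relaxation sets in.
#'
#' @param epoch an EEG [signal_trace()].
#' @param seg_s Welch segment length in seconds (default 2 within the
#'   epoch; the epoch itself is 8 s by default upstream).
#' @param alpha,beta band edges in Hz.
#' @return An object of class `band_power_pair`: list with `alpha_power`,
#'   `beta_power` (uV^2) and the band edges.
#' @export
eeg_band_power <- function(epoch, seg_s = 2, alpha = c(8, 12),
                           beta = c(14, 25)) {
  stopifnot(inherits(epoch, "signal_trace"))
  M <- min(length(epoch), max(16L, floor(seg_s * epoch$fs)))
  psd <- welch_psd(epoch, welch_spec(M = M, fs = epoch$fs))
  structure(list(alpha_power = band_power(psd, alpha[1], alpha[2]),
                 beta_power = band_power(psd, beta[1], beta[2]),
                 alpha_band = alpha, beta_band = beta),
            class = "band_power_pair")
}

#' Drowsiness score for an EEG epoch
#'
#' Computes the alpha/beta Welch band-power ratio of the epoch and flags
#' drowsiness when the ratio exceeds `threshold_mult` times the baseline
#' ratio (the driver's own eyes-open reference). A vanishing beta power
#' makes the ratio indeterminate; this is flagged, not an error.
#'
#' @param eeg_epoch an EEG [signal_trace()], nominally >= 8 s.
#' @param baseline a `band_power_pair` from the calibration period.
#' @param threshold_mult ratio multiplier above baseline that counts as
#'   drowsy (default 1.5).
#' @return An object of class `drowsiness_score`: `ratio`,
#'   `baseline_ratio`, `drowsy` (logical, `NA` if indeterminate),
#'   `indeterminate`, `alpha_power`, `beta_power`.
#' @export
drowsiness_score <- function(eeg_epoch, baseline, threshold_mult = 1.5) {
  stopifnot(inherits(baseline, "band_power_pair"))
  bp <- eeg_band_power(eeg_epoch, alpha = baseline$alpha_band,
                       beta = baseline$beta_band)
  indeterminate <- bp$beta_power <= 0 || baseline$beta_power <= 0
  ratio <- if (bp$beta_power > 0) bp$alpha_power / bp$beta_power else NA_real_
  baseline_ratio <- if (baseline$beta_power > 0) {
    baseline$alpha_power / baseline$beta_power
  } else NA_real_
  drowsy <- if (indeterminate) NA else ratio > threshold_mult * baseline_ratio
  structure(list(ratio = ratio, baseline_ratio = baseline_ratio,
                 drowsy = drowsy, indeterminate = indeterminate,
                 alpha_power = bp$alpha_power, beta_power = bp$beta_power,
                 threshold_mult = threshold_mult),
            class = "drowsiness_score")
}
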