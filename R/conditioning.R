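#' Filter specification
#'
#' Declarative description of a conditioning filter, validated against the
#' sampling rate at application time. Four kinds are supported:
#' `"notch"` (second-order IIR, centre `f0`, quality factor `q_factor`),
#' `"bandpass"` and `"lowpass"` (Butterworth of the given order) and
#' `"moving_average"` (centred sliding mean of `window_len` samples, the
#' smoother applied ahead of the Butterworth band-pass).
#'
#' @param kind one of `"notch"`, `"bandpass"`, `"lowpass"`,
#'   `"moving_average"`.
#' @param f0 notch centre frequency, Hz.
#' @param f_lo,f_hi band-pass edges, Hz (`f_hi` alone for lowpass).
#' @param order Butterworth order (default 4).
#' @param q_factor notch quality factor (default 30).
#' @param window_len moving-average window, samples (odd; default 5).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("notch", "bandpass", "lowpass",
                                 "moving_average"),
                        f0 = NULL, f_lo = NULL, f_hi = NULL, order = 4,
                        q_factor = 30, window_len = 5) {
  kind <- match.arg(kind)
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  if (kind == "notch" && (is.null(f0) || f0 <= 0)) {
    stop("notch requires a positive `f0`", call. = FALSE)
  }
  if (kind == "bandpass" &&
      (is.null(f_lo) || is.null(f_hi) || f_lo < 0 || f_hi <= f_lo)) {
    stop("bandpass requires 0 <= f_lo < f_hi", call. = FALSE)
  }
  if (kind == "lowpass" && (is.null(f_hi) || f_hi <= 0)) {
    stop("lowpass requires a positive `f_hi`", call. = FALSE)
  }
  if (kind == "moving_average" && (window_len < 1)) {
    stop("`window_len` must be >= 1", call. = FALSE)
  }
  structure(list(kind = kind, f0 = f0, f_lo = f_lo, f_hi = f_hi,
                 order = order, q_factor = q_factor,
                 window_len = as.integer(window_len)),
            class = "filter_spec")
}

# RBJ-cookbook second-order notch biquad (b, a), normalized.
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply a conditioning filter, zero-phase
#'
#' IIR designs (notch, Butterworth band-pass/low-pass) are applied
#' forward-backward ([signal::filtfilt()]) so the net filter has zero phase
#' and no group delay; the moving average is a centred symmetric window and
#' is zero-phase by construction. Output length equals input length.
#'
#' @param trace a [signal_trace()].
#' @param spec a [filter_spec()]; all cutoffs must lie strictly inside
#'   `(0, fs/2)`.
#' @return The filtered [signal_trace()].
#' @examples
#' tr <- signal_trace(sin(2 * pi * 50 * seq(0, 1, 1 / 500)), fs = 500)
#' out <- apply_filter(tr, filter_spec("notch", f0 = 50))
#' @export
apply_filter <- function(trace, spec) {
  stopifnot(inherits(trace, "signal_trace"), inherits(spec, "filter_spec"))
  fs <- trace$fs
  nyq <- fs / 2
  x <- trace$samples
  if (!length(x)) return(trace)
  y <- switch(spec$kind,
    notch = {
      if (spec$f0 >= nyq) stop("notch `f0` must be < fs/2", call. = FALSE)
      co <- notch_coefs(spec$f0, fs, spec$q_factor)
      signal::filtfilt(signal::Arma(b = co$b, a = co$a), x)
    },
    bandpass = {
      if (spec$f_hi >= nyq) stop("`f_hi` must be < fs/2", call. = FALSE)
      # A 0 Hz lower edge means high-frequency cutoff only.
      if (spec$f_lo <= 0) {
        bt <- signal::butter(spec$order, spec$f_hi / nyq, type = "low")
      } else {
        bt <- signal::butter(max(1L, round(spec$order / 2)),
                             c(spec$f_lo, spec$f_hi) / nyq, type = "pass")
      }
      signal::filtfilt(bt, x)
    },
    lowpass = {
      if (spec$f_hi >= nyq) stop("`f_hi` must be < fs/2", call. = FALSE)
      bt <- signal::butter(spec$order, spec$f_hi / nyq, type = "low")
      signal::filtfilt(bt, x)
    },
    moving_average = {
      k <- spec$window_len
      if (k %% 2L == 0L) k <- k + 1L
      stats::filter(x, rep(1 / k, k), sides = 2) |>
        (\(v) { v[is.na(v)] <- x[is.na(v)]; as.numeric(v) })()
    }
  )
  trace_with(trace, y)
}

#' Wavelet specification
#'
#' Parameters for the dyadic wavelet machinery: family (Haar only — the
#' family used throughout), number of decomposition levels, and the
#' detail-coefficient thresholding rule for denoising. `"universal"`
#' derives the threshold from the data (`sigma_hat * sqrt(2 * log(N))`,
#' with `sigma_hat` the median absolute deviation of the level-1 details
#' divided by 0.6745); `"fixed"` takes explicit per-level values.
#'
#' @param family wavelet family; only `"haar"` is implemented.
#' @param levels decomposition depth (>= 1; default 3).
#' @param threshold_rule `"universal"` or `"fixed"`.
#' @param threshold_values per-level thresholds for `"fixed"` (recycled if
#'   length 1).
#' @param mode `"soft"` (shrinkage) or `"hard"` (keep/kill).
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = "haar", levels = 3,
                         threshold_rule = c("universal", "fixed"),
                         threshold_values = NULL,
                         mode = c("soft", "hard")) {
  if (!identical(tolower(family), "haar")) {
    stop("unknown wavelet family: ", family, call. = FALSE)
  }
  threshold_rule <- match.arg(threshold_rule)
  mode <- match.arg(mode)
  if (levels < 1) stop("`levels` must be >= 1", call. = FALSE)
  if (threshold_rule == "fixed" && is.null(threshold_values)) {
    stop("`threshold_values` required for the fixed rule", call. = FALSE)
  }
  structure(list(family = "haar", levels = as.integer(levels),
                 threshold_rule = threshold_rule,
                 threshold_values = threshold_values, mode = mode),
            class = "wavelet_spec")
}

#' Orthonormal Haar basis vectors
#'
#' Constructs the explicit discrete Haar basis of R^n for a `levels`-deep
#' dyadic decomposition: the scaled step functions `psi_{j,k}` (value
#' `+2^(-j/2)` on the first half of their support, `-2^(-j/2)` on the
#' second) plus the coarse scaling vectors. Rows are pairwise orthonormal.
#' Used both as the reference implementation of the dyadic transform and to
#' verify orthonormality directly.
#'
#' @param n signal length (a multiple of `2^levels`).
#' @param levels decomposition depth.
#' @return An `n x n` matrix whose rows are the basis vectors, ordered as
#'   scaling vectors first, then details from coarsest (`j = levels`) to
#'   finest (`j = 1`).
#' @export
haar_basis <- function(n, levels) {
  if (n %% 2^levels != 0) {
    stop("`n` must be a multiple of 2^levels", call. = FALSE)
  }
  rows <- list()
  # coarse scaling functions at scale `levels`
  blk <- 2^levels
  for (k in seq_len(n / blk)) {
    v <- numeric(n)
    v[((k - 1) * blk + 1):(k * blk)] <- 2^(-levels / 2)
    rows[[length(rows) + 1L]] <- v
  }
  for (j in seq(levels, 1)) {
    blk <- 2^j
    for (k in seq_len(n / blk)) {
      v <- numeric(n)
      i0 <- (k - 1) * blk
      v[(i0 + 1):(i0 + blk / 2)] <- 2^(-j / 2)
      v[(i0 + blk / 2 + 1):(i0 + blk)] <- -2^(-j / 2)
      rows[[length(rows) + 1L]] <- v
    }
  }
  do.call(rbind, rows)
}

#' Decimated dyadic Haar wavelet coefficients
#'
#' Classical (decimated) discrete wavelet decomposition with the Haar
#' filter pair: at each level, approximation `(x[2k-1] + x[2k]) / sqrt(2)`
#' and detail `(x[2k-1] - x[2k]) / sqrt(2)`. The coefficients equal the
#' inner products of the signal with the orthonormal Haar family of
#' [haar_basis()], so total energy is preserved (Parseval).
#'
#' @param trace a non-empty [signal_trace()] whose length is a multiple of
#'   `2^levels` (no implicit padding here; see [swt_denoise()] for padded
#'   processing).
#' @param spec a [wavelet_spec()].
#' @return A list with `approx` (level-`levels` approximation coefficients)
#'   and `details`, a list of detail-coefficient vectors from level 1
#'   (finest) to `levels`.
#' @export
dwt_coeffs <- function(trace, spec) {
  stopifnot(inherits(trace, "signal_trace"), inherits(spec, "wavelet_spec"))
  x <- trace$samples
  n <- length(x)
  if (n == 0L) stop("`trace` must be non-empty", call. = FALSE)
  if (n %% 2^spec$levels != 0) {
    stop("length must be a multiple of 2^levels (", 2^spec$levels, ")",
         call. = FALSE)
  }
  details <- vector("list", spec$levels)
  a <- x
  for (j in seq_len(spec$levels)) {
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details)
}

# --- stationary (undecimated) Haar transform -------------------------------

# Forward SWT, periodic boundary. Returns list(approx, details[[j]]), each
# full-length. Shift step at level j is 2^(j-1).
swt_forward <- function(x, levels) {
  n <- length(x)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- 2^(j - 1)
    lag <- a[((seq_len(n) - 1 - s) %% n) + 1]
    details[[j]] <- (a - lag) / sqrt(2)
    a <- (a + lag) / sqrt(2)
  }
  list(approx = a, details = details)
}

# Inverse SWT, averaging the two consistent reconstructions at each level.
swt_inverse <- function(coeffs) {
  a <- coeffs$approx
  levels <- length(coeffs$details)
  n <- length(a)
  for (j in seq(levels, 1)) {
    d <- coeffs$details[[j]]
    s <- 2^(j - 1)
    lead_a <- a[((seq_len(n) - 1 + s) %% n) + 1]
    lead_d <- d[((seq_len(n) - 1 + s) %% n) + 1]
    a <- ((a + d) + (lead_a - lead_d)) / (2 * sqrt(2))
  }
  a
}

soft_threshold <- function(d, lambda) sign(d) * pmax(abs(d) - lambda, 0)
hard_threshold <- function(d, lambda) d * (abs(d) > lambda)

#' Stationary-wavelet denoising (Haar SWT, thresholded details)
#'
#' Undecimated (stationary) Haar wavelet transform to `spec$levels` levels,
#' per-level thresholding of the detail coefficients (soft shrinkage by
#' default), inverse transform. The transform uses periodic boundary
#' handling, which makes denoising exactly equivariant to circular shifts;
#' when the signal length is not a multiple of `2^levels` it is first
#' extended by symmetric reflection and the output is cut back, so output
#' length always equals input length. With all thresholds zero the
#' round-trip is the identity (perfect reconstruction).
#'
#' @param trace a non-empty [signal_trace()].
#' @param spec a [wavelet_spec()]; the default (`haar`, 3 levels, soft
#'   universal threshold) is the recommended ECG denoiser.
#' @return The denoised [signal_trace()].
#' @examples
#' clean <- gen_ecg(ecg_profile(), 5, fs = 500, seed = 1)
#' noisy <- trace_with_noise(clean, snr_db = 5, seed = 2)
#' den <- swt_denoise(noisy, wavelet_spec())
#' @export
swt_denoise <- function(trace, spec = wavelet_spec()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(spec, "wavelet_spec"))
  x <- trace$samples
  n <- length(x)
  if (n == 0L) stop("`trace` must be non-empty", call. = FALSE)
  blk <- 2^spec$levels
  pad <- (blk - n %% blk) %% blk
  if (pad > 0) {
    # symmetric reflection extension
    refl <- rev(x)[seq_len(min(pad, n))]
    refl <- rep_len(refl, pad)
    xx <- c(x, refl)
  } else {
    xx <- x
  }
  co <- swt_forward(xx, spec$levels)
  lambda <- switch(spec$threshold_rule,
    universal = {
      sigma <- stats::median(abs(co$details[[1]])) / 0.6745
      rep(sigma * sqrt(2 * log(length(xx))), spec$levels)
    },
    fixed = rep_len(as.numeric(spec$threshold_values), spec$levels)
  )
  thr <- if (spec$mode == "soft") soft_threshold else hard_threshold
  for (j in seq_len(spec$levels)) {
    co$details[[j]] <- thr(co$details[[j]], lambda[j])
  }
  y <- swt_inverse(co)
  trace_with(trace, y[seq_len(n)])
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Convenience fixture for denoising experiments: adds zero-mean white
#' noise scaled so the signal-to-noise ratio is `snr_db` decibels.
#'
#' @param trace a [signal_trace()].
#' @param snr_db desired SNR in dB.
#' @param seed integer seed.
#' @return The noisy [signal_trace()].
#' @export
trace_with_noise <- function(trace, snr_db, seed = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  p_sig <- mean(trace$samples^2)
  p_noise <- p_sig / 10^(snr_db / 10)
  with_seed(seed, {
    trace_with(trace, trace$samples +
                 sqrt(p_noise) * stats::rnorm(length(trace)))
  })
}
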