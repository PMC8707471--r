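#' R-peak detection (derivative-square-integrate detector)
#'
#' Pan-Tompkins-style QRS detector: band-pass 5-15 Hz to emphasize the QRS
#' complex, differentiate, square, integrate over a 150 ms moving window,
#' pick local maxima separated by at least the 250 ms refractory period,
#' keep those above an adaptive threshold that tracks running signal and
#' noise levels (accept above `noise + (signal - noise)/4`, with
#' exponential updates of both levels), and finally refine each detection
#' to the
#' largest absolute excursion of the band-passed signal within +-50 ms.
#' The detector is invariant to positive rescaling of the input.
#'
#' @param trace an ECG [signal_trace()], `fs >= 250`, ideally conditioned
#'   (notch + band-pass) first.
#' @param refractory_s minimum inter-beat spacing in seconds (default
#'   0.25).
#' @return An object of class `beat_series`: `r_indices` (sample
#'   positions, strictly increasing), `rr_s` (inter-beat intervals),
#'   `hr_bpm` (`60 / mean(rr_s)`), `irregularity` (coefficient of
#'   variation of the RR intervals). A trace with fewer than two
#'   detectable beats yields an empty series with a warning.
#' @examples
#' ecg <- gen_ecg(ecg_profile(hr_bpm = 60), 10, fs = 500, seed = 1)
#' beats <- detect_r_peaks(ecg)
#' beats$hr_bpm
#' @export
detect_r_peaks <- function(trace, refractory_s = 0.25) {
  stopifnot(inherits(trace, "signal_trace"))
  fs <- trace$fs
  if (fs < 250) stop("`fs` must be >= 250 Hz", call. = FALSE)
  empty <- structure(list(r_indices = integer(0), rr_s = numeric(0),
                          hr_bpm = NA_real_, irregularity = NA_real_,
                          fs = fs),
                     class = "beat_series")
  n <- length(trace)
  if (n < fs) { warning("trace shorter than two beats"); return(empty) }
  x <- trace$samples
  if (all(x == x[1])) { warning("flat trace: no beats"); return(empty) }
  # QRS emphasis band
  bp <- apply_filter(trace, filter_spec("bandpass", f_lo = 5, f_hi = 15,
                                        order = 4))$samples
  d <- c(0, diff(bp))
  sq <- d^2
  wlen <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  integ[is.na(integ)] <- 0
  refr <- max(1L, round(refractory_s * fs))
  cand <- local_maxima(integ, min_dist = refr)
  if (length(cand) < 2L) { warning("fewer than two beats detected"); return(empty) }
  heights <- integ[cand]
  # adaptive threshold: running signal/noise level tracking. The signal
  # level follows accepted QRS peaks, the noise level everything else;
  # a candidate qualifies above noise + 1/4 of the signal-noise gap.
  spki <- max(heights[cand <= 2 * fs], heights[1])
  npki <- stats::median(heights)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    thr <- npki + 0.25 * (spki - npki)
    if (heights[i] > thr) {
      keep[i] <- TRUE
      spki <- 0.125 * heights[i] + 0.875 * spki
    } else {
      npki <- 0.125 * heights[i] + 0.875 * npki
    }
  }
  cand <- cand[keep]
  if (length(cand) < 2L) { warning("fewer than two beats detected"); return(empty) }
  # refine to the biggest band-passed excursion within +-50 ms
  half <- max(1L, round(0.05 * fs))
  r_idx <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce refractory after refinement
  if (length(r_idx) > 1L) {
    keep <- c(TRUE, diff(r_idx) >= refr)
    r_idx <- r_idx[keep]
  }
  rr <- diff(r_idx) / fs
  structure(list(r_indices = r_idx, rr_s = rr,
                 hr_bpm = 60 / mean(rr),
                 irregularity = stats::sd(rr) / mean(rr),
                 fs = fs),
            class = "beat_series")
}

# Indices of strict local maxima separated by at least `min_dist` samples,
# greedily keeping the taller peak within each exclusion window.
local_maxima <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx) || min_dist <= 1L) return(idx)
  ord <- idx[order(x[idx], decreasing = TRUE)]
  taken <- logical(n)
  out <- integer(0)
  for (i in ord) {
    lo <- max(1L, i - min_dist + 1L); hi <- min(n, i + min_dist - 1L)
    if (!any(taken[lo:hi])) { taken[i] <- TRUE; out <- c(out, i) }
  }
  sort(out)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, hr=%.1f bpm, RR CV=%.3f\n",
              length(x$r_indices), x$hr_bpm, x$irregularity))
  invisible(x)
}

#' Default heart-rate bands
#'
#' Half-open `[lo, hi)` bands: normal 70-90 bpm; red candidates 40-60 and
#' 100-120 bpm (and anything beyond those outer limits); everything else
#' outside normal is yellow. A lone heart rate inside a red band is still
#' only a phase-3 (yellow) alert at the fusion stage — escalation to red
#' requires a second violated metric.
#'
#' @param normal,red_low,red_high two-element `c(lo, hi)` bounds in bpm.
#' @param arrhythmia_cv RR coefficient-of-variation threshold above which
#'   the rhythm is flagged irregular (default 0.15).
#' @return A list of band definitions used by [classify_rate()].
#' @export
hr_bands <- function(normal = c(70, 90), red_low = c(40, 60),
                     red_high = c(100, 120), arrhythmia_cv = 0.15) {
  list(normal = normal, red_low = red_low, red_high = red_high,
       arrhythmia_cv = arrhythmia_cv)
}

#' Classify a beat series into rate bands
#'
#' Labels the mean heart rate as `normal`, `yellow_rate` or `red_rate`
#' against configurable bands (red wins where red and yellow definitions
#' overlap, e.g. 100-120 bpm), and raises the arrhythmia flag when the RR
#' coefficient of variation exceeds its threshold.
#'
#' @param beats a `beat_series` from [detect_r_peaks()].
#' @param bands band configuration from [hr_bands()].
#' @return A list: `label`, `hr_bpm`, `arrhythmia`.
#' @export
classify_rate <- function(beats, bands = hr_bands()) {
  stopifnot(inherits(beats, "beat_series"))
  hr <- beats$hr_bpm
  if (!length(beats$r_indices) || !is.finite(hr)) {
    stop("empty beat series cannot be classified", call. = FALSE)
  }
  in_band <- function(v, b) v >= b[1] & v < b[2]
  label <- if (in_band(hr, bands$normal)) {
    "normal"
  } else if (in_band(hr, bands$red_low) || in_band(hr, bands$red_high) ||
             hr < bands$red_low[1] || hr >= bands$red_high[2]) {
    "red_rate"
  } else {
    "yellow_rate"
  }
  arr <- is.finite(beats$irregularity) &&
    beats$irregularity > bands$arrhythmia_cv
  list(label = label, hr_bpm = hr, arrhythmia = arr)
}
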