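#' Default SpO2 calibration table
#'
#' Monotone conversion table mapping the ratio-of-ratios `R` to oxygen
#' saturation. Device vendors burn an empirically fitted table into
#' firmware; no such table is published for the sensor modelled here, so
#' the package ships the textbook linear approximation
#' `SpO2 = 110 - 25 R` sampled at 2.5 % knots over 70-100 %, exposed as an
#' ordinary table so user-supplied CSV tables drop in unchanged. `R`
#' increases as saturation falls.
#'
#' @return A data frame with columns `R` (strictly increasing) and `spo2`.
#' @export
default_calibration_table <- function() {
  spo2 <- seq(100, 70, by = -2.5)
  data.frame(R = (110 - spo2) / 25, spo2 = spo2)
}

check_calibration_table <- function(table) {
  if (!is.data.frame(table) || !all(c("R", "spo2") %in% names(table)) ||
      nrow(table) < 2L) {
    stop("calibration table needs columns R, spo2 and >= 2 rows",
         call. = FALSE)
  }
  if (any(diff(table$R) <= 0) && any(diff(table$R) >= 0)) {
    stop("calibration table R column must be strictly monotone",
         call. = FALSE)
  }
  if (any(table$spo2 <= 0 | table$spo2 > 100)) {
    stop("calibration spo2 values must lie in (0, 100]", call. = FALSE)
  }
  invisible(table)
}

# Inverse lookup used by the PPG generator: SpO2 -> R via the same
# piecewise-linear table.
ratio_for_spo2 <- function(spo2, table = default_calibration_table()) {
  check_calibration_table(table)
  if (spo2 < min(table$spo2) || spo2 > max(table$spo2)) {
    stop("`spo2_true` outside the calibration table domain", call. = FALSE)
  }
  ord <- order(table$spo2)
  stats::approx(table$spo2[ord], table$R[ord], xout = spo2,
                ties = "ordered")$y
}

#' Extract pulsatile (AC) and baseline (DC) components of a PPG pair
#'
#' Per channel: DC is the windowed mean; AC is the mean beat-wise
#' peak-to-trough amplitude, measured between successive pulse peaks
#' (local maxima separated by at least the period of a 180 bpm pulse).
#' A window without a detectable pulse yields `AC = 0`, which downstream
#' code flags as indeterminate rather than erroring.
#'
#' @param ppg a `ppg_pair` from [gen_ppg_pair()] (or built manually with
#'   `red`/`ir` [signal_trace()]s of equal length and rate).
#' @param window_s analysis window in seconds, taken from the start of the
#'   pair (default: full length). Should contain at least two beats.
#' @return An object of class `pulsatile_components`: `i_ac_red`,
#'   `i_dc_red`, `i_ac_ir`, `i_dc_ir`.
#' @export
extract_ac_dc <- function(ppg, window_s = NULL) {
  stopifnot(inherits(ppg, "ppg_pair") ||
              (is.list(ppg) && inherits(ppg$red, "signal_trace")))
  if (ppg$red$fs != ppg$ir$fs || length(ppg$red) != length(ppg$ir)) {
    stop("red and IR channels must share fs and length", call. = FALSE)
  }
  fs <- ppg$red$fs
  n <- if (is.null(window_s)) length(ppg$red) else
    min(length(ppg$red), floor(window_s * fs))
  one <- function(x) {
    x <- x[seq_len(n)]
    dc <- mean(x)
    if (dc <= 0) stop("non-positive DC level: sensor fault", call. = FALSE)
    min_dist <- max(2L, round(fs * 60 / 180))
    pk <- local_maxima(x, min_dist = min_dist)
    if (length(pk) < 2L) return(c(ac = 0, dc = dc))
    p2t <- vapply(seq_len(length(pk) - 1L), function(i) {
      seg <- x[pk[i]:pk[i + 1L]]
      max(seg) - min(seg)
    }, numeric(1))
    c(ac = mean(p2t), dc = dc)
  }
  r <- one(ppg$red$samples); ir <- one(ppg$ir$samples)
  structure(list(i_ac_red = unname(r["ac"]), i_dc_red = unname(r["dc"]),
                 i_ac_ir = unname(ir["ac"]), i_dc_ir = unname(ir["dc"])),
            class = "pulsatile_components")
}

#' Ratio of ratios
#'
#' The red-to-infrared absorption ratio in its log form:
#' `R = log(I_AC_R / I_DC_R) / log(I_AC_IR / I_DC_IR)`. Both logarithms
#' are negative for physiological modulation depths (AC < DC), so `R` is
#' positive. `R` is invariant to common per-channel rescaling of (AC, DC).
#' A zero AC on either channel makes the ratio indeterminate (`NA` with
#' attribute `indeterminate`), distinguishing a lost pulse from a
#' computational error.
#'
#' @param pc a `pulsatile_components` from [extract_ac_dc()].
#' @return Scalar `R` (or `NA` flagged indeterminate).
#' @export
ratio_R <- function(pc) {
  stopifnot(inherits(pc, "pulsatile_components"))
  if (pc$i_dc_red <= 0 || pc$i_dc_ir <= 0) {
    stop("DC components must be positive", call. = FALSE)
  }
  if (pc$i_ac_red == 0 || pc$i_ac_ir == 0) {
    return(structure(NA_real_, indeterminate = TRUE))
  }
  if (pc$i_ac_red < 0 || pc$i_ac_ir < 0) {
    stop("AC components must be non-negative", call. = FALSE)
  }
  mr <- pc$i_ac_red / pc$i_dc_red
  mi <- pc$i_ac_ir / pc$i_dc_ir
  if (mr >= 1 || mi >= 1) {
    stop("AC must be smaller than DC on both channels", call. = FALSE)
  }
  log(mr) / log(mi)
}

#' Convert a ratio-of-ratios value to SpO2
#'
#' Piecewise-linear interpolation over the calibration table. Values of
#' `R` outside the table domain are clamped to the nearest knot with a
#' warning (a real device saturates its display the same way).
#'
#' @param R ratio-of-ratios value (scalar).
#' @param table calibration table (default
#'   [default_calibration_table()]).
#' @return SpO2 in percent, or `NA` if `R` is indeterminate.
#' @export
spo2_from_ratio <- function(R, table = default_calibration_table()) {
  check_calibration_table(table)
  if (is.na(R)) return(NA_real_)
  if (R < min(table$R) || R > max(table$R)) {
    warning("R outside calibration table domain; clamped")
    R <- min(max(R, min(table$R)), max(table$R))
  }
  ord <- order(table$R)
  stats::approx(table$R[ord], table$spo2[ord], xout = R,
                ties = "ordered")$y
}

#' Full SpO2 estimation pipeline
#'
#' AC/DC extraction, ratio of ratios, table lookup — optionally smoothed
#' with a running median over successive windows to avoid single-window
#' flicker before alerting.
#'
#' @param ppg a `ppg_pair`.
#' @param table calibration table.
#' @param window_s analysis window in seconds; `NULL` processes the whole
#'   pair as one window.
#' @param smooth_windows length of the median smoother across windows
#'   (default 3; only relevant when `window_s` yields several windows).
#' @return A list: `spo2` (percent, the smoothed final estimate), `R`,
#'   `per_window` (data frame of window estimates), `indeterminate`.
#' @examples
#' est <- estimate_spo2(gen_ppg_pair(95, duration_s = 10, fs = 250, seed = 1))
#' est$spo2
#' @export
estimate_spo2 <- function(ppg, table = default_calibration_table(),
                          window_s = NULL, smooth_windows = 3) {
  fs <- ppg$red$fs
  n <- length(ppg$red)
  if (is.null(window_s) || floor(window_s * fs) >= n) {
    pc <- extract_ac_dc(ppg)
    R <- ratio_R(pc)
    return(list(spo2 = spo2_from_ratio(R, table), R = as.numeric(R),
                per_window = NULL,
                indeterminate = isTRUE(attr(R, "indeterminate"))))
  }
  wlen <- floor(window_s * fs)
  starts <- seq(1L, n - wlen + 1L, by = wlen)
  est <- vapply(starts, function(s) {
    sub <- list(red = trace_with(ppg$red, ppg$red$samples[s:(s + wlen - 1)]),
                ir = trace_with(ppg$ir, ppg$ir$samples[s:(s + wlen - 1)]))
    class(sub) <- "ppg_pair"
    R <- ratio_R(extract_ac_dc(sub))
    c(spo2_from_ratio(R, table), as.numeric(R))
  }, numeric(2))
  spo2_w <- est[1, ]; R_w <- est[2, ]
  ok <- !is.na(spo2_w)
  smoothed <- if (sum(ok) == 0) NA_real_ else {
    v <- spo2_w[ok]
    k <- min(smooth_windows, length(v))
    if (k %% 2 == 0) k <- k - 1
    if (k >= 3) stats::median(utils::tail(stats::runmed(v, k), 1)) else
      utils::tail(v, 1)
  }
  list(spo2 = smoothed, R = utils::tail(R_w[ok], 1),
       per_window = data.frame(window = seq_along(starts), spo2 = spo2_w,
                               R = R_w),
       indeterminate = all(!ok))
}

#' Read a calibration table from CSV
#'
#' Expects columns `R,spo2`; validated for monotonicity and range.
#' @param path CSV path.
#' @return The validated calibration data frame.
#' @export
read_calibration_csv <- function(path) {
  tab <- utils::read.csv(path)
  check_calibration_table(tab)
  tab
}
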