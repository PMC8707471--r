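#' 8x8 thermal frame
#'
#' One timestamped frame from the 64-point thermopile array. Pixels are
#' indexed row-major `p00..p77` (`pRC` = row R, column C, zero-based).
#'
#' @param temps 8x8 numeric matrix (or length-64 vector, filled row-major)
#'   of surface temperatures in degC; all finite, within -20..1000.
#' @param time_s timestamp in seconds.
#' @return An object of class `thermal_frame`: list with `temps` (8x8
#'   matrix) and `time_s`.
#' @export
thermal_frame <- function(temps, time_s = 0) {
  if (is.vector(temps)) {
    if (length(temps) != 64L) stop("need exactly 64 values", call. = FALSE)
    temps <- matrix(as.numeric(temps), 8, 8, byrow = TRUE)
  }
  if (!is.matrix(temps) || !all(dim(temps) == c(8L, 8L))) {
    stop("`temps` must be an 8x8 matrix", call. = FALSE)
  }
  if (any(!is.finite(temps))) stop("all temperatures must be finite",
                                   call. = FALSE)
  if (any(temps < -20 | temps > 1000)) {
    stop("temperatures outside the plausible -20..1000 degC range",
         call. = FALSE)
  }
  structure(list(temps = temps, time_s = as.numeric(time_s)),
            class = "thermal_frame")
}

#' Thermal alarm configuration
#'
#' Thresholds for the overheat/flame classifier. A cabin reaches the 40
#' degC critical temperature within minutes on a hot day, which motivates
#' the default `critical_temp` and a warming-rate threshold of about 40
#' degC / 8 min = 0.04 degC/s. Flames are distinguished by large
#' frame-to-frame pixel jumps (default 15 degC) or outright flame-level
#' temperatures (default 80 degC).
#'
#' @param warn_temp early-warning temperature, degC (default 35).
#' @param critical_temp overheat threshold, degC (default 40).
#' @param flame_temp absolute flame-level temperature, degC (default 80).
#' @param flame_jump per-frame pixel increase that signals flame, degC
#'   (default 15).
#' @param warming_rate temperature slope that signals warming, degC/s
#'   (default 0.04).
#' @param gradient_window number of trailing frames over which slopes are
#'   fitted (default 20).
#' @param regions named list of logical 8x8 masks (or cell-index vectors)
#'   for per-region statistics; default none.
#' @return An object of class `thermal_config`.
#' @export
thermal_config <- function(warn_temp = 35, critical_temp = 40,
                           flame_temp = 80, flame_jump = 15,
                           warming_rate = 0.04, gradient_window = 20,
                           regions = list()) {
  if (!(warn_temp < critical_temp && critical_temp < flame_temp)) {
    stop("need warn_temp < critical_temp < flame_temp", call. = FALSE)
  }
  structure(list(warn_temp = warn_temp, critical_temp = critical_temp,
                 flame_temp = flame_temp, flame_jump = flame_jump,
                 warming_rate = warming_rate,
                 gradient_window = as.integer(gradient_window),
                 regions = regions),
            class = "thermal_config")
}

region_mask <- function(region) {
  if (is.logical(region)) {
    if (!all(dim(region) == c(8L, 8L))) {
      stop("logical region masks must be 8x8", call. = FALSE)
    }
    return(region)
  }
  idx <- as.integer(region)
  if (any(idx < 1L | idx > 64L)) {
    stop("region indices reference pixels outside the 8x8 grid",
         call. = FALSE)
  }
  m <- matrix(FALSE, 8, 8)
  m[idx] <- TRUE
  m
}

#' Per-region statistics of a thermal frame
#'
#' Maximum, mean and arg-max pixel for every named region plus the whole
#' frame.
#'
#' @param frame a [thermal_frame()].
#' @param regions named list of masks (logical 8x8 matrices or cell-index
#'   vectors in column-major matrix order).
#' @return A data frame with columns `region`, `max_c`, `mean_c`,
#'   `argmax_row`, `argmax_col` (zero-based, matching the `pRC` naming).
#' @export
frame_stats <- function(frame, regions = list()) {
  stopifnot(inherits(frame, "thermal_frame"))
  g <- frame$temps
  one <- function(name, mask) {
    v <- g[mask]
    sel <- which(mask & g == max(v), arr.ind = TRUE)
    data.frame(region = name, max_c = max(v), mean_c = mean(v),
               argmax_row = sel[1, 1] - 1L, argmax_col = sel[1, 2] - 1L)
  }
  out <- one("frame", matrix(TRUE, 8, 8))
  for (nm in names(regions)) {
    out <- rbind(out, one(nm, region_mask(regions[[nm]])))
  }
  rownames(out) <- NULL
  out
}

#' Per-pixel temporal temperature gradient
#'
#' Least-squares slope of each pixel's temperature against time over the
#' trailing `window` frames.
#'
#' @param frames list of [thermal_frame()]s with strictly increasing
#'   timestamps (>= 2).
#' @param window number of trailing frames to fit (default: all).
#' @return An 8x8 matrix of slopes in degC/s.
#' @export
temporal_gradient <- function(frames, window = length(frames)) {
  if (length(frames) < 2L) stop("need >= 2 frames", call. = FALSE)
  times <- vapply(frames, function(f) f$time_s, numeric(1))
  if (any(diff(times) <= 0)) {
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  }
  use <- utils::tail(seq_along(frames), max(2L, window))
  tt <- times[use]
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  acc <- matrix(0, 8, 8)
  for (i in seq_along(use)) {
    acc <- acc + tc[i] * frames[[use[i]]]$temps
  }
  acc / denom
}

#' Classify a thermal frame sequence
#'
#' Precedence flame > overheat > warming > ambient:
#' * `flame` when any pixel's frame-to-frame increase reaches
#'   `flame_jump`, or any pixel reaches `flame_temp`;
#' * `overheat` when any pixel (or configured region) reaches
#'   `critical_temp`;
#' * `warming` when any pixel's fitted temperature slope reaches
#'   `warming_rate` and is also statistically distinguishable from pixel
#'   noise (at least four standard errors of the fitted slope), so that
#'   sensor noise over short windows does not raise spurious warming
#'   alerts;
#' * `ambient` otherwise.
#'
#' @param frames list of [thermal_frame()]s (>= 2, monotone timestamps).
#' @param config a [thermal_config()].
#' @return A list: `label`, `trigger_pixels` (data frame `row`/`col`,
#'   zero-based, possibly empty), `max_temp`, `max_jump`, `max_slope`.
#' @export
classify_thermal <- function(frames, config = thermal_config()) {
  if (length(frames) < 2L) stop("need >= 2 frames", call. = FALSE)
  stopifnot(inherits(config, "thermal_config"))
  cube <- vapply(frames, function(f) f$temps, matrix(0, 8, 8))
  max_temp <- apply(cube, c(1, 2), max)
  jumps <- cube[, , -1, drop = FALSE] - cube[, , -dim(cube)[3], drop = FALSE]
  max_jump <- apply(jumps, c(1, 2), max)
  slope <- temporal_gradient(frames, config$gradient_window)
  flame_px <- max_jump >= config$flame_jump | max_temp >= config$flame_temp
  hot_px <- max_temp >= config$critical_temp
  # standard error of each pixel's slope from the residuals of the fit
  use <- utils::tail(seq_along(frames), max(2L, config$gradient_window))
  tt <- vapply(frames[use], function(f) f$time_s, numeric(1))
  tc <- tt - mean(tt)
  ssx <- sum(tc^2)
  fitted_sse <- matrix(0, 8, 8)
  mean_t <- apply(cube[, , use, drop = FALSE], c(1, 2), mean)
  for (i in seq_along(use)) {
    resid <- cube[, , use[i]] - mean_t - slope * tc[i]
    fitted_sse <- fitted_sse + resid^2
  }
  dfree <- max(1L, length(use) - 2L)
  slope_se <- sqrt(fitted_sse / dfree / ssx)
  warm_px <- slope >= config$warming_rate &
    (slope_se == 0 | slope >= 4 * slope_se)
  pick <- function(mask) {
    sel <- which(mask, arr.ind = TRUE)
    data.frame(row = sel[, 1] - 1L, col = sel[, 2] - 1L)
  }
  if (any(flame_px)) {
    label <- "flame"; trig <- pick(flame_px)
  } else if (any(hot_px)) {
    label <- "overheat"; trig <- pick(hot_px)
  } else if (any(warm_px)) {
    label <- "warming"; trig <- pick(warm_px)
  } else {
    label <- "ambient"; trig <- data.frame(row = integer(0), col = integer(0))
  }
  list(label = label, trigger_pixels = trig,
       max_temp = max(max_temp), max_jump = max(max_jump),
       max_slope = max(slope))
}

#' Severity order of thermal labels
#'
#' `ambient < warming < overheat < flame`; useful for monotonicity checks
#' and alert fusion.
#' @param label character vector of thermal labels.
#' @return Integer severities 0-3.
#' @export
thermal_severity <- function(label) {
  match(label, c("ambient", "warming", "overheat", "flame")) - 1L
}
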