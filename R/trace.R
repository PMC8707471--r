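#' Uniformly sampled single-channel signal
#'
#' `signal_trace` is the carrier type for every acquired or synthesized
#' signal in the package: a numeric sample vector together with its sampling
#' rate, physical units and channel label. All processing functions accept
#' and return this class so that sampling-rate bookkeeping never leaks into
#' user code.
#'
#' @param samples numeric vector of amplitudes. Units are microvolts for EEG,
#'   millivolts for ECG and arbitrary intensity for PPG.
#' @param fs sampling rate in Hz (> 0). The package default is 1000 Hz, the
#'   rate used for capacitive EEG acquisition.
#' @param channel label string, e.g. `"ecg"`, `"eeg"`, `"ppg_red"`.
#' @param units unit string carried for display and CSV round-trips.
#' @param t0 start time in seconds.
#'
#' @return An object of class `signal_trace`: a list with elements
#'   `samples`, `fs`, `channel`, `units`, `t0`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), fs = 250)
#' length(tr)
#' @export
signal_trace <- function(samples, fs, channel = "signal", units = "a.u.",
                         t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs, channel = as.character(channel)[1L],
         units = as.character(units)[1L], t0 = as.numeric(t0)[1L]),
    class = "signal_trace"
  )
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Time axis of a trace, in seconds
#' @param trace a [signal_trace()].
#' @return numeric vector `t0 + (0:(n-1))/fs`.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  if (!length(trace)) return(numeric(0))
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

#' Duration of a trace, in seconds
#' @param trace a [signal_trace()].
#' @export
trace_duration <- function(trace) length(trace) / trace$fs

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> channel=%s  n=%d  fs=%g Hz  dur=%.3f s  units=%s\n",
              x$channel, length(x), x$fs, trace_duration(x), x$units))
  invisible(x)
}

# Replace the sample vector, keeping metadata. Internal.
trace_with <- function(trace, samples) {
  trace$samples <- as.numeric(samples)
  trace
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
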