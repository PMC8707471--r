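#' Write / read a signal trace as annotated CSV
#'
#' Dialect: `#`-prefixed header lines carrying `fs`, `units` and
#' `channel`, then two columns `time_s,value`. The time column must be
#' uniform and monotone; round-trips are lossless to the written decimal
#' precision (15 significant digits).
#'
#' @param trace a [signal_trace()].
#' @param path file path.
#' @return `write_signal_csv` invisibly returns `path`; `read_signal_csv`
#'   returns the reconstructed [signal_trace()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_signal_csv(signal_trace(rnorm(10), fs = 100), f)
#' tr <- read_signal_csv(f)
#' @export
write_signal_csv <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", trace$fs),
               sprintf("# units=%s", trace$units),
               sprintf("# channel=%s", trace$channel),
               "time_s,value"), con)
  if (length(trace)) {
    writeLines(sprintf("%.15g,%.15g", trace_time(trace), trace$samples), con)
  }
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  if (is.null(meta$fs)) stop("signal CSV missing `fs` header", call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("time_s", "value") %in% names(dat))) {
    stop("signal CSV must have columns time_s,value", call. = FALSE)
  }
  fs <- as.numeric(meta$fs)
  if (nrow(dat) > 1) {
    dt <- diff(dat$time_s)
    if (any(dt <= 0)) stop("non-monotone time column", call. = FALSE)
    if (max(abs(dt - 1 / fs)) > 1e-6 / fs) {
      stop("time column is not uniform at the declared fs", call. = FALSE)
    }
  }
  signal_trace(dat$value, fs = fs,
               channel = meta$channel %||% "signal",
               units = meta$units %||% "a.u.",
               t0 = if (nrow(dat)) dat$time_s[1] else 0)
}

#' Write / read a thermal frame sequence as CSV
#'
#' Columns `time_s,p00,p01,...,p77` (row-major pixel naming `pRC`), one
#' row per frame.
#'
#' @param frames list of [thermal_frame()]s.
#' @param path file path.
#' @return `write_thermal_csv` invisibly returns `path`;
#'   `read_thermal_csv` returns the list of frames.
#' @export
write_thermal_csv <- function(frames, path) {
  px <- as.vector(t(outer(0:7, 0:7, function(r, c) sprintf("p%d%d", r, c))))
  rows <- vapply(frames, function(f) {
    paste(c(sprintf("%.10g", f$time_s),
            sprintf("%.10g", as.vector(t(f$temps)))), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("time_s", px), collapse = ","), rows), path)
  invisible(path)
}

#' @rdname write_thermal_csv
#' @export
read_thermal_csv <- function(path) {
  dat <- utils::read.csv(path)
  px <- as.vector(t(outer(0:7, 0:7, function(r, c) sprintf("p%d%d", r, c))))
  if (!all(c("time_s", px) %in% names(dat))) {
    stop("thermal CSV must have columns time_s,p00..p77", call. = FALSE)
  }
  lapply(seq_len(nrow(dat)), function(i) {
    thermal_frame(as.numeric(dat[i, px]), time_s = dat$time_s[i])
  })
}

#' Append typed events to a JSONL log
#'
#' One JSON object per line: `time_s`, `source`, `severity`, `payload`.
#' The log is append-only and time-ordered within a run; alerting side
#' effects (sound, display, vehicle-to-vehicle broadcast) are reduced to
#' these records.
#'
#' @param events list of event records (each a list with `time_s`,
#'   `source`, `severity`, `payload`).
#' @param path JSONL file path.
#' @param append append to an existing log (default `FALSE`).
#' @return invisibly, `path`.
#' @export
write_events_jsonl <- function(events, path, append = FALSE) {
  lines <- vapply(events, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA))
  }, character(1))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Read a JSONL event log
#' @param path JSONL file path.
#' @return list of event records.
#' @export
read_events_jsonl <- function(path) {
  lapply(readLines(path), jsonlite::fromJSON)
}

#' Default run configuration
#'
#' Nested configuration for the monitoring pipeline, with sections
#' `conditioning`, `eeg`, `ecg`, `oximetry`, `thermal`, `alerting` and
#' `classifier`. Every default is the module default documented on the
#' corresponding constructor. Serializable to JSON via [write_config()] /
#' [read_config()]; unknown keys are rejected at read time.
#'
#' @param seed integer seed for the run.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    conditioning = list(notch_hz = 50, bandpass = c(0.5, 35),
                        swt_levels = 3, swt_mode = "soft"),
    eeg = list(alpha_band = c(8, 12), beta_band = c(14, 25),
               epoch_s = 8, drowsy_threshold_mult = 1.5,
               drowsy_persistence_epochs = 2),
    ecg = list(bands = hr_bands()),
    oximetry = list(table = "default", smooth_windows = 3),
    thermal = list(critical_temp = 40, flame_temp = 80, flame_jump = 15,
                   warming_rate = 0.04),
    alerting = list(persistence_s = 10, ring_buffer_s = 30,
                    training_s = 60),
    classifier = list(K = 12, hidden = 8)
  ), class = "run_config")
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  ref <- unclass(default_config())
  unknown <- setdiff(names(raw), names(ref))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merged <- utils::modifyList(ref, raw)
  structure(merged, class = "run_config")
}
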