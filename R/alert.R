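#' Fused per-window vitals snapshot
#'
#' One row of the fused metric stream consumed by the alert state machine.
#' Missing metrics are explicitly `NA`, never silently zero.
#'
#' @param time_s timestamp, seconds from stream start.
#' @param hr_bpm heart rate (bpm) or `NA`.
#' @param spo2_pct oxygen saturation (percent) or `NA`.
#' @param drowsy logical drowsiness flag or `NA`.
#' @param arrhythmia logical irregular-rhythm flag or `NA`.
#' @param eeg_state cognitive-state label or `NA`.
#' @param thermal_label thermal classification label or `NA`.
#' @param impact logical collision flag.
#' @return A one-row data frame of class `vitals_snapshot`.
#' @export
vitals_snapshot <- function(time_s, hr_bpm = NA_real_, spo2_pct = NA_real_,
                            drowsy = NA, arrhythmia = NA,
                            eeg_state = NA_character_,
                            thermal_label = NA_character_, impact = FALSE) {
  out <- data.frame(time_s = as.numeric(time_s), hr_bpm = as.numeric(hr_bpm),
                    spo2_pct = as.numeric(spo2_pct), drowsy = as.logical(drowsy),
                    arrhythmia = as.logical(arrhythmia),
                    eeg_state = as.character(eeg_state),
                    thermal_label = as.character(thermal_label),
                    impact = isTRUE(impact))
  class(out) <- c("vitals_snapshot", class(out))
  out
}

#' Bind snapshots into a stream
#' @param ... `vitals_snapshot` rows or data frames of them.
#' @return A time-ordered data frame (validation errors on non-monotone
#'   timestamps).
#' @export
snapshot_stream <- function(...) {
  s <- do.call(rbind, lapply(list(...), as.data.frame))
  if (is.unsorted(s$time_s, strictly = FALSE)) {
    stop("snapshot timestamps must be monotone", call. = FALSE)
  }
  s
}

#' Per-metric banding and persistence configuration
#'
#' Normal / yellow / red bands for each fused metric, the persistence
#' window a violation must hold before it escalates an alert, and the
#' pre-impact ring-buffer span. Defaults follow the worked thresholds of
#' the five-phase scheme: pulse normal 70-90 bpm, red candidates 40-60 and
#' 100-120 bpm (red still requires a second violated metric); oximetry
#' normal 95-100 %, yellow 90-94 %, red below 90 % (bounds inclusive).
#' Drowsiness, arrhythmia and thermal overheat/flame each count as one
#' maximal-threshold metric.
#'
#' @param hr heart-rate bands from [hr_bands()].
#' @param spo2_normal,spo2_yellow inclusive SpO2 bands, percent.
#' @param persistence_s seconds a violation must persist before escalation
#'   (default 10).
#' @param ring_buffer_s pre-impact retention span, seconds (default 30).
#' @param training_s duration of the phase-1 calibration period, seconds
#'   (default 60).
#' @return An object of class `phase_config`.
#' @export
phase_config <- function(hr = hr_bands(), spo2_normal = c(95, 100),
                         spo2_yellow = c(90, 94), persistence_s = 10,
                         ring_buffer_s = 30, training_s = 60) {
  if (persistence_s <= 0) stop("`persistence_s` must be > 0", call. = FALSE)
  structure(list(hr = hr, spo2_normal = spo2_normal,
                 spo2_yellow = spo2_yellow,
                 persistence_s = persistence_s,
                 ring_buffer_s = ring_buffer_s, training_s = training_s),
            class = "phase_config")
}

#' Learn per-driver normal bands from a baseline stream
#'
#' Phase-1 calibration: the normal band for each continuous metric is
#' `mean +- k * sd`, clipped so it never extends past the default bands'
#' outer yellow limits (heart rate kept within 60-100 bpm, SpO2 within
#' 90-100 %). An empty or too-short baseline falls back to the printed
#' defaults with a warning. Calibration is deterministic, so repeating it
#' on the same stream reproduces the same configuration.
#'
#' @param baseline_stream data frame of snapshots (see
#'   [snapshot_stream()]) covering at least `min_duration_s`.
#' @param k band half-width in standard deviations (default 3).
#' @param min_duration_s minimum baseline coverage (default 30 s).
#' @param defaults fallback [phase_config()].
#' @return A [phase_config()] with personalized normal bands.
#' @export
calibrate <- function(baseline_stream, k = 3, min_duration_s = 30,
                      defaults = phase_config()) {
  cfg <- defaults
  if (is.null(baseline_stream) || !nrow(baseline_stream) ||
      diff(range(baseline_stream$time_s)) < min_duration_s) {
    warning("insufficient baseline; using default bands")
    return(cfg)
  }
  hr <- baseline_stream$hr_bpm[is.finite(baseline_stream$hr_bpm)]
  if (length(hr) >= 2L) {
    band <- mean(hr) + c(-1, 1) * k * stats::sd(hr)
    cfg$hr$normal <- c(max(band[1], 60), min(band[2], 100))
  }
  sp <- baseline_stream$spo2_pct[is.finite(baseline_stream$spo2_pct)]
  if (length(sp) >= 2L) {
    band <- mean(sp) + c(-1, 1) * k * stats::sd(sp)
    cfg$spo2_normal <- c(max(band[1], 90), min(band[2], 100))
  }
  cfg
}

# Band classification of one snapshot. Returns a named integer vector of
# violation levels per metric: 0 normal/unknown, 1 yellow, 2 red-candidate.
snapshot_bands <- function(snap, config) {
  lev <- c(hr = 0L, spo2 = 0L, drowsy = 0L, arrhythmia = 0L, thermal = 0L)
  hr <- snap$hr_bpm
  if (is.finite(hr)) {
    b <- config$hr
    if (hr >= b$normal[1] && hr < b$normal[2]) {
      lev["hr"] <- 0L
    } else if ((hr >= b$red_low[1] && hr < b$red_low[2]) ||
               (hr >= b$red_high[1] && hr < b$red_high[2]) ||
               hr < b$red_low[1] || hr >= b$red_high[2]) {
      lev["hr"] <- 2L
    } else {
      lev["hr"] <- 1L
    }
  }
  sp <- snap$spo2_pct
  if (is.finite(sp)) {
    if (sp >= config$spo2_normal[1]) {
      lev["spo2"] <- 0L
    } else if (sp >= config$spo2_yellow[1]) {
      lev["spo2"] <- 1L
    } else {
      lev["spo2"] <- 2L
    }
  }
  if (isTRUE(snap$drowsy)) lev["drowsy"] <- 2L
  if (isTRUE(snap$arrhythmia)) lev["arrhythmia"] <- 2L
  th <- snap$thermal_label
  if (!is.na(th)) {
    sev <- thermal_severity(th)
    if (is.finite(sev)) {
      lev["thermal"] <- if (sev >= 2L) 2L else if (sev == 1L) 1L else 0L
    }
  }
  lev
}

#' Evaluate the five-phase alert state machine over a snapshot history
#'
#' Pure function of `(history, config)`. Phases:
#' 1. training — while the stream is still inside the configured
#'    calibration window (only when `training = TRUE`);
#' 2. normal (green) — no sustained violation;
#' 3. alert (yellow) — at least one metric outside its normal band,
#'    sustained for `persistence_s`;
#' 4. alert (red) — at least two metrics simultaneously in maximal
#'    (red) bands, each sustained for `persistence_s`;
#' 5. collision — the impact flag was observed (sticky; overrides
#'    everything).
#'
#' A heart rate inside the red 100-120 bpm band with no second violated
#' metric therefore raises only a phase-3 alert. De-escalation is
#' hysteretic: a phase drops only after its trigger has been absent for
#' `persistence_s`.
#'
#' @param history time-ordered data frame of snapshots.
#' @param config a [phase_config()].
#' @param training logical: treat the first `training_s` of the stream as
#'   the phase-1 calibration window (default `FALSE`).
#' @return An object of class `alert_decision` for the final snapshot:
#'   `phase` (1-5), `color`, `triggers` (data frame metric/value/band),
#'   `since` (time the current phase was entered). The full per-snapshot
#'   decision sequence is attached as attribute `"sequence"` (integer
#'   phases), so streaming replay and batch evaluation coincide by
#'   construction.
#' @export
evaluate <- function(history, config = phase_config(), training = FALSE) {
  if (is.null(history) || !nrow(history)) stop("empty history", call. = FALSE)
  if (is.unsorted(history$time_s, strictly = FALSE)) {
    stop("history must be time-ordered", call. = FALSE)
  }
  n <- nrow(history)
  times <- history$time_s
  lev <- t(vapply(seq_len(n), function(i) snapshot_bands(history[i, ], config),
                  integer(5)))
  colnames(lev) <- c("hr", "spo2", "drowsy", "arrhythmia", "thermal")
  t0 <- times[1]
  persistence <- config$persistence_s
  # For each metric, the start time of the current uninterrupted violation
  # run at each snapshot (NA when not violated).
  sustained_at <- function(i, min_level) {
    vapply(seq_len(ncol(lev)), function(m) {
      j <- i
      while (j >= 1 && lev[j, m] >= min_level) j <- j - 1
      if (j == i) return(FALSE)
      times[i] - times[j + 1] >= persistence
    }, logical(1))
  }
  phases <- integer(n)
  impact_seen <- FALSE
  phase_prev <- 2L
  last_high <- -Inf  # last time the raw phase was >= phase_prev
  for (i in seq_len(n)) {
    impact_seen <- impact_seen || isTRUE(history$impact[i])
    if (impact_seen) {
      phases[i] <- 5L
      phase_prev <- 5L
      next
    }
    if (training && times[i] - t0 < config$training_s) {
      phases[i] <- 1L
      phase_prev <- 1L
      next
    }
    red_sus <- sustained_at(i, 2L)
    any_sus <- sustained_at(i, 1L)
    raw <- if (sum(red_sus) >= 2L) 4L else if (any(any_sus)) 3L else 2L
    # hysteresis: drop below the previous phase only after persistence_s
    # of calm
    if (raw >= phase_prev || phase_prev <= 2L) {
      phases[i] <- raw
      if (raw >= phase_prev) last_high <- times[i]
      phase_prev <- phases[i]
    } else {
      if (times[i] - last_high >= persistence) {
        phases[i] <- raw
        phase_prev <- raw
        last_high <- times[i]
      } else {
        phases[i] <- phase_prev
      }
    }
  }
  final <- phases[n]
  colors <- c("training", "green", "yellow", "red", "collision")
  # triggers: metrics violated at the final snapshot
  lv <- lev[n, ]
  trig_m <- names(lv)[lv > 0L]
  triggers <- data.frame(
    metric = trig_m,
    value = vapply(trig_m, function(m) switch(m,
      hr = history$hr_bpm[n], spo2 = history$spo2_pct[n],
      drowsy = 1, arrhythmia = 1,
      thermal = thermal_severity(history$thermal_label[n])), numeric(1)),
    band = ifelse(lv[trig_m] == 2L, "red", "yellow"),
    row.names = NULL
  )
  since_idx <- n
  while (since_idx > 1 && phases[since_idx - 1] == final) {
    since_idx <- since_idx - 1
  }
  structure(list(phase = final, color = colors[final],
                 triggers = triggers, since = times[since_idx]),
            class = "alert_decision",
            sequence = phases)
}

#' @export
print.alert_decision <- function(x, ...) {
  cat(sprintf("<alert_decision> phase %d (%s) since t=%.1f s; %d trigger(s)\n",
              x$phase, x$color, x$since, nrow(x$triggers)))
  invisible(x)
}

#' Maintain the pre-impact ring buffer
#'
#' Appends a snapshot and drops everything older than `ring_buffer_s`
#' before the newest timestamp (boundary inclusive: a snapshot exactly
#' `ring_buffer_s` old is retained). The result is independent of how
#' snapshots were batched on arrival.
#'
#' @param buffer data frame of buffered snapshots (or `NULL`).
#' @param snapshot the incoming snapshot row (or data frame of rows).
#' @param ring_buffer_s retention span in seconds (default 30).
#' @return The updated buffer data frame.
#' @export
update_ring_buffer <- function(buffer, snapshot, ring_buffer_s = 30) {
  buf <- if (is.null(buffer)) as.data.frame(snapshot) else
    rbind(as.data.frame(buffer), as.data.frame(snapshot))
  if (is.unsorted(buf$time_s, strictly = FALSE)) {
    stop("snapshot times must be monotone", call. = FALSE)
  }
  newest <- max(buf$time_s)
  buf <- buf[buf$time_s >= newest - ring_buffer_s, , drop = FALSE]
  rownames(buf) <- NULL
  buf
}

#' Assemble the e-Call payload
#'
#' Minimum-data-set style emergency payload issued on a phase-5 decision:
#' vehicle identity, occupant count, the ring-buffered pre-impact
#' snapshots in time order, vehicle dynamics placeholders (`NA` when the
#' bus feed is absent — marked null in JSON, never omitted), position and
#' the collision timestamp. Serializes losslessly through
#' [payload_to_json()] / [payload_from_json()].
#'
#' @param buffer ring-buffer data frame of pre-impact snapshots.
#' @param vehicle_meta list with at least `vehicle_id`; optional
#'   `occupant_count` (default 1), `speed_mps`, `heading_deg`.
#' @param position list with `lat`, `lon` (decimal degrees).
#' @param timestamp collision time, seconds.
#' @return An object of class `ecall_payload`.
#' @export
build_ecall_payload <- function(buffer, vehicle_meta, position,
                                timestamp = max(buffer$time_s)) {
  if (is.null(vehicle_meta$vehicle_id)) {
    stop("`vehicle_meta$vehicle_id` is required", call. = FALSE)
  }
  structure(list(
    schema = "ecall-payload/1",
    vehicle_id = as.character(vehicle_meta$vehicle_id),
    occupant_count = as.integer(vehicle_meta$occupant_count %||% 1L),
    pre_impact_snapshots = as.data.frame(buffer),
    dynamics = list(speed_mps = vehicle_meta$speed_mps %||% NA_real_,
                    heading_deg = vehicle_meta$heading_deg %||% NA_real_),
    position = list(lat = position$lat %||% NA_real_,
                    lon = position$lon %||% NA_real_),
    timestamp = as.numeric(timestamp)
  ), class = "ecall_payload")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / deserialize an e-Call payload
#'
#' JSON round-trip with nulls preserved for missing dynamics.
#' @param payload an `ecall_payload`.
#' @param json JSON string from [payload_to_json()].
#' @return `payload_to_json`: a JSON string; `payload_from_json`: the
#'   reconstructed `ecall_payload`.
#' @export
payload_to_json <- function(payload) {
  stopifnot(inherits(payload, "ecall_payload"))
  jsonlite::toJSON(unclass(payload), auto_unbox = TRUE, null = "null",
                   na = "null", digits = NA)
}

#' @rdname payload_to_json
#' @export
payload_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json)
  raw$pre_impact_snapshots <- as.data.frame(raw$pre_impact_snapshots)
  raw$occupant_count <- as.integer(raw$occupant_count)
  raw$dynamics <- list(speed_mps = raw$dynamics$speed_mps %||% NA_real_,
                       heading_deg = raw$dynamics$heading_deg %||% NA_real_)
  raw$position <- list(lat = raw$position$lat %||% NA_real_,
                       lon = raw$position$lon %||% NA_real_)
  structure(raw, class = "ecall_payload")
}
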