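#' Generate a named synthetic drive scenario
#'
#' Produces the multi-channel inputs for one simulated drive:
#' * `quiet_drive` — eyes-open EEG, normal-rate ECG, 98 % SpO2, ambient
#'   cabin;
#' * `drowsy_onset` — identical start, but the EEG switches to the drowsy
#'   alpha-dominant mixture halfway through the drive;
#' * `collision` — quiet drive ending with an impact flag on the final
#'   vitals window.
#'
#' @param scenario scenario name.
#' @param duration_s drive duration in seconds (default 120).
#' @param fs sampling rate for the physiological channels (default 250 Hz
#'   to keep simulated drives light; the acquisition default of 1000 Hz
#'   works identically).
#' @param seed integer seed.
#' @return A list: `ecg`, `eeg` (traces), `ppg` (pair), `thermal` (frame
#'   list), `impact_time_s` (`NA` unless a collision occurs), `scenario`,
#'   `fs`.
#' @export
gen_scenario <- function(scenario = c("quiet_drive", "drowsy_onset",
                                      "collision"),
                         duration_s = 120, fs = 250, seed = 1) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  half <- duration_s / 2
  eeg <- if (scenario == "drowsy_onset") {
    a <- gen_eeg(eeg_state_spec("eyes_open"), half, fs, seed = seed + 11L)
    b <- gen_eeg(eeg_state_spec("drowsy"), duration_s - half, fs,
                 seed = seed + 12L)
    trace_with(a, c(a$samples, b$samples))
  } else {
    gen_eeg(eeg_state_spec("eyes_open"), duration_s, fs, seed = seed + 11L)
  }
  list(
    scenario = scenario, fs = fs,
    ecg = gen_ecg(ecg_profile("normal", hr_bpm = 75), duration_s, fs,
                  seed = seed + 21L),
    eeg = eeg,
    ppg = gen_ppg_pair(98, hr_bpm = 75, duration_s = duration_s, fs = fs,
                       seed = seed + 31L),
    thermal = gen_thermal_sequence("ambient",
                                   n_frames = max(2L, round(duration_s * 10)),
                                   fps = 10, seed = seed + 41L),
    impact_time_s = if (scenario == "collision") duration_s else NA_real_
  )
}

# Extract a sub-trace [t_lo, t_hi) by time. Internal.
trace_window <- function(trace, t_lo, t_hi) {
  i_lo <- max(1L, floor(t_lo * trace$fs) + 1L)
  i_hi <- min(length(trace), ceiling(t_hi * trace$fs))
  trace_with(trace, trace$samples[i_lo:i_hi])
}

#' Run the end-to-end monitoring pipeline
#'
#' Wires all modules into the cooperative-alerting flow: the raw channels
#' are conditioned (notch + band-pass for ECG), vitals are fused on
#' 10-second tumbling windows (heart rate and rhythm from R-peak
#' detection, SpO2 from the oximetry pipeline, drowsiness from 8-second
#' EEG epochs against the first window's baseline with 2-epoch
#' persistence, thermal label per window), and the snapshot stream is
#' folded through the five-phase alert state machine. A collision
#' produces exactly one e-Call payload carrying the ring-buffered
#' pre-impact snapshots. Given the same config, scenario and seed, two
#' runs produce byte-identical event logs.
#'
#' @param config a `run_config` from [default_config()].
#' @param scenario scenario name passed to [gen_scenario()], or a
#'   pre-built scenario list (e.g. loaded from CSV inputs).
#' @param duration_s drive duration when generating (default 120 s).
#' @param vehicle_meta passed to [build_ecall_payload()] on collision.
#' @param position ditto.
#' @return A list of class `monitor_run`: `snapshots` (fused stream),
#'   `decisions` (per-snapshot phase integers), `final` (last
#'   [evaluate()] decision), `events` (list of event records), `payload`
#'   (an `ecall_payload` or `NULL`).
#' @examples
#' \donttest{
#' run <- run_monitor(default_config(seed = 7), "quiet_drive",
#'                    duration_s = 60)
#' run$final
#' }
#' @export
run_monitor <- function(config = default_config(), scenario = "quiet_drive",
                        duration_s = 120,
                        vehicle_meta = list(vehicle_id = "TEST-VEH-1",
                                            occupant_count = 1),
                        position = list(lat = 44.43, lon = 26.10)) {
  stopifnot(inherits(config, "run_config"))
  sc <- if (is.character(scenario)) {
    gen_scenario(scenario, duration_s = duration_s, seed = config$seed)
  } else scenario
  fs_set <- unique(c(sc$ecg$fs, sc$eeg$fs, sc$ppg$red$fs))
  if (length(fs_set) != 1L) {
    stop("inconsistent sampling rates across channels", call. = FALSE)
  }
  dur <- trace_duration(sc$ecg)
  win_s <- 10
  epoch_s <- config$eeg$epoch_s
  # conditioning: notch + band-pass on the ECG channel
  ecg_c <- apply_filter(sc$ecg, filter_spec("notch",
                                            f0 = config$conditioning$notch_hz))
  ecg_c <- apply_filter(ecg_c, filter_spec("bandpass",
                                           f_lo = config$conditioning$bandpass[1],
                                           f_hi = config$conditioning$bandpass[2]))
  # EEG baseline: eyes-open reference averaged over the first three
  # epochs of the drive, for a stable personal ratio
  baseline <- eeg_band_power(trace_window(sc$eeg, 0, min(3 * epoch_s, dur)),
                             alpha = config$eeg$alpha_band,
                             beta = config$eeg$beta_band)
  times_th <- vapply(sc$thermal, function(f) f$time_s, numeric(1))
  starts <- seq(0, dur - win_s, by = win_s)
  events <- list()
  snaps <- NULL
  buffer <- NULL
  drowsy_run <- 0L
  for (w0 in starts) {
    w1 <- w0 + win_s
    beats <- suppressWarnings(detect_r_peaks(trace_window(ecg_c, w0, w1)))
    hr <- beats$hr_bpm
    arr <- FALSE
    if (length(beats$r_indices)) {
      cls <- classify_rate(beats, config$ecg$bands)
      arr <- cls$arrhythmia
    }
    sub_ppg <- structure(list(red = trace_window(sc$ppg$red, w0, w1),
                              ir = trace_window(sc$ppg$ir, w0, w1)),
                         class = "ppg_pair")
    spo2 <- estimate_spo2(sub_ppg)$spo2
    # drowsiness on the trailing epoch of the window, 2-epoch persistence
    ep <- trace_window(sc$eeg, max(0, w1 - epoch_s), w1)
    ds <- drowsiness_score(ep, baseline, config$eeg$drowsy_threshold_mult)
    drowsy_run <- if (isTRUE(ds$drowsy)) drowsy_run + 1L else 0L
    drowsy <- drowsy_run >= config$eeg$drowsy_persistence_epochs
    th_idx <- which(times_th >= w0 & times_th < w1)
    th_label <- if (length(th_idx) >= 2L) {
      classify_thermal(sc$thermal[th_idx],
                       thermal_config(critical_temp = config$thermal$critical_temp,
                                      flame_temp = config$thermal$flame_temp,
                                      flame_jump = config$thermal$flame_jump,
                                      warming_rate = config$thermal$warming_rate))$label
    } else NA_character_
    impact <- is.finite(sc$impact_time_s) && w1 >= sc$impact_time_s
    snap <- vitals_snapshot(time_s = w1, hr_bpm = hr, spo2_pct = spo2,
                            drowsy = drowsy, arrhythmia = arr,
                            thermal_label = th_label, impact = impact)
    snaps <- if (is.null(snaps)) as.data.frame(snap) else
      rbind(snaps, as.data.frame(snap))
    buffer <- update_ring_buffer(buffer, snap,
                                 config$alerting$ring_buffer_s)
    events[[length(events) + 1L]] <- list(
      time_s = w1, source = "fusion", severity = "info",
      payload = list(hr_bpm = hr, spo2_pct = spo2, drowsy = drowsy,
                     thermal = th_label))
  }
  pc <- phase_config(hr = config$ecg$bands,
                     persistence_s = config$alerting$persistence_s,
                     ring_buffer_s = config$alerting$ring_buffer_s,
                     training_s = config$alerting$training_s)
  final <- evaluate(snaps, pc)
  decisions <- attr(final, "sequence")
  for (i in seq_along(decisions)) {
    if (decisions[i] >= 3L) {
      events[[length(events) + 1L]] <- list(
        time_s = snaps$time_s[i], source = "alert_engine",
        severity = c("info", "info", "warning", "critical",
                     "collision")[decisions[i]],
        payload = list(phase = decisions[i]))
    }
  }
  payload <- NULL
  if (final$phase == 5L) {
    payload <- build_ecall_payload(buffer, vehicle_meta, position,
                                   timestamp = max(snaps$time_s))
    events[[length(events) + 1L]] <- list(
      time_s = max(snaps$time_s), source = "ecall", severity = "collision",
      payload = list(schema = payload$schema,
                     snapshots = nrow(payload$pre_impact_snapshots)))
  }
  ord <- order(vapply(events, function(e) e$time_s, numeric(1)))
  structure(list(snapshots = snaps, decisions = decisions, final = final,
                 events = events[ord], payload = payload),
            class = "monitor_run")
}

#' @export
print.monitor_run <- function(x, ...) {
  cat(sprintf("<monitor_run> %d windows; phases: %s; final phase %d (%s)\n",
              nrow(x$snapshots),
              paste(rle(x$decisions)$values, collapse = " -> "),
              x$final$phase, x$final$color))
  invisible(x)
}
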