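# Build a 1 Hz snapshot stream with constant metrics.
const_stream <- function(duration_s, hr = 80, spo2 = 98, drowsy = FALSE,
                         arrhythmia = FALSE, impact_at = NULL) {
  rows <- lapply(0:(duration_s - 1), function(tt) {
    vitals_snapshot(time_s = tt, hr_bpm = hr, spo2_pct = spo2,
                    drowsy = drowsy, arrhythmia = arrhythmia,
                    impact = !is.null(impact_at) && tt >= impact_at)
  })
  do.call(snapshot_stream, rows)
}

test_that("phase assignment follows the five-phase thresholds", {
  cfg <- phase_config()

  # all-normal stream stays green
  expect_equal(evaluate(const_stream(60), cfg)$phase, 2L)

  # a single sustained violation (hr 105, spo2 96) is a yellow alert
  d3 <- evaluate(const_stream(60, hr = 105, spo2 = 96), cfg)
  expect_equal(d3$phase, 3L)
  expect_equal(d3$color, "yellow")
  expect_true("hr" %in% d3$triggers$metric)

  # two sustained maximal violations (hr 110, spo2 88) are a red alert
  d4 <- evaluate(const_stream(60, hr = 110, spo2 = 88), cfg)
  expect_equal(d4$phase, 4L)
  expect_setequal(d4$triggers$metric, c("hr", "spo2"))

  # impact dominates everything
  d5 <- evaluate(const_stream(30, impact_at = 29), cfg)
  expect_equal(d5$phase, 5L)
  expect_equal(d5$color, "collision")
  d5b <- evaluate(const_stream(30, hr = 110, spo2 = 88, impact_at = 0), cfg)
  expect_equal(d5b$phase, 5L)

  # drowsiness plus a red heart rate also escalates to red
  d4b <- evaluate(const_stream(60, hr = 110, drowsy = TRUE), cfg)
  expect_equal(d4b$phase, 4L)

  # training window maps to phase 1
  d1 <- evaluate(const_stream(30), cfg, training = TRUE)
  expect_equal(d1$phase, 1L)
})

test_that("violations must persist to escalate, and phases are sticky", {
  cfg <- phase_config(persistence_s = 10)
  # 5 s violation inside a 60 s stream: never beyond green
  rows <- lapply(0:59, function(tt) {
    vitals_snapshot(tt, hr_bpm = if (tt >= 20 && tt < 25) 110 else 80,
                    spo2_pct = 98, drowsy = FALSE, arrhythmia = FALSE)
  })
  s <- do.call(snapshot_stream, rows)
  expect_equal(max(attr(evaluate(s, cfg), "sequence")), 2L)

  # a 15 s violation escalates, then de-escalates only after calm
  rows2 <- lapply(0:59, function(tt) {
    vitals_snapshot(tt, hr_bpm = if (tt >= 10 && tt < 25) 110 else 80,
                    spo2_pct = 98, drowsy = FALSE, arrhythmia = FALSE)
  })
  seq2 <- attr(evaluate(do.call(snapshot_stream, rows2), cfg), "sequence")
  expect_equal(max(seq2), 3L)
  expect_equal(seq2[21], 3L)          # sustained at t = 20
  expect_equal(seq2[30], 3L)          # hysteresis holds just after recovery
  expect_equal(seq2[60], 2L)          # calm long enough: back to green

  # monotonicity: adding a red violation never lowers the phase
  base <- const_stream(60, hr = 105, spo2 = 96)
  esc <- const_stream(60, hr = 105, spo2 = 88)
  expect_gte(evaluate(esc)$phase, evaluate(base)$phase)
})

test_that("evaluation is pure and replay-equivalent", {
  s <- const_stream(40, hr = 110, spo2 = 88)
  d1 <- evaluate(s)
  d2 <- evaluate(s)
  expect_identical(d1, d2)

  # streaming prefix-by-prefix equals the batch sequence
  batch_seq <- attr(evaluate(s), "sequence")
  stream_seq <- vapply(seq_len(nrow(s)), function(k) {
    evaluate(s[1:k, , drop = FALSE])$phase
  }, integer(1))
  expect_identical(stream_seq, batch_seq)

  expect_error(evaluate(s[c(2, 1), ]), "time-ordered")
  expect_error(evaluate(s[0, ]), "empty")
})

test_that("calibration learns per-driver bands and falls back safely", {
  set.seed(5)
  rows <- lapply(0:59, function(tt) {
    vitals_snapshot(tt, hr_bpm = rnorm(1, 75, 3), spo2_pct = rnorm(1, 98, 0.4),
                    drowsy = FALSE, arrhythmia = FALSE)
  })
  base <- do.call(snapshot_stream, rows)
  cfg <- calibrate(base)
  expect_lte(cfg$hr$normal[1], 70)
  expect_gte(cfg$hr$normal[2], 80)
  expect_gte(cfg$hr$normal[1], 60)
  expect_lte(cfg$hr$normal[2], 100)

  # deterministic: recalibrating on the same stream gives the same config
  expect_identical(calibrate(base), cfg)

  expect_warning(fallback <- calibrate(base[1:5, ]), "insufficient")
  expect_identical(fallback$hr$normal, phase_config()$hr$normal)
})

test_that("ring buffer retains exactly the trailing window", {
  buf <- NULL
  for (tt in 0:59) {
    buf <- update_ring_buffer(buf, vitals_snapshot(tt, hr_bpm = 80,
                                                   spo2_pct = 98),
                              ring_buffer_s = 30)
  }
  expect_equal(nrow(buf), 31)  # boundary inclusive
  expect_equal(range(buf$time_s), c(29, 59))

  one <- update_ring_buffer(NULL, vitals_snapshot(0, hr_bpm = 80))
  expect_equal(nrow(one), 1)

  # batching independence
  s <- const_stream(45)
  b1 <- NULL
  for (k in seq_len(nrow(s))) b1 <- update_ring_buffer(b1, s[k, ], 30)
  b2 <- update_ring_buffer(update_ring_buffer(NULL, s[1:40, ], 30),
                           s[41:45, ], 30)
  expect_equal(b1, b2)
})

test_that("e-Call payload carries the pre-impact record and round-trips", {
  buf <- const_stream(30)
  pay <- build_ecall_payload(buf, list(vehicle_id = "B-123-XYZ",
                                       occupant_count = 2),
                             list(lat = 44.43, lon = 26.10),
                             timestamp = 29)
  expect_equal(nrow(pay$pre_impact_snapshots), 30)
  expect_identical(pay$pre_impact_snapshots$time_s, buf$time_s)
  expect_equal(pay$occupant_count, 2L)
  expect_true(is.na(pay$dynamics$speed_mps))  # marked null, never omitted

  js <- payload_to_json(pay)
  expect_match(as.character(js), '"speed_mps":null', fixed = TRUE)
  back <- payload_from_json(js)
  expect_equal(back$vehicle_id, pay$vehicle_id)
  expect_equal(back$occupant_count, pay$occupant_count)
  expect_equal(back$pre_impact_snapshots$hr_bpm,
               pay$pre_impact_snapshots$hr_bpm)
  expect_equal(back$position$lat, 44.43)

  expect_error(build_ecall_payload(buf, list(occupant_count = 1),
                                   list(lat = 0, lon = 0)), "vehicle_id")
})
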