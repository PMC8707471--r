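test_that("frame statistics: uniform, point source, brute-force regions", {
  uni <- thermal_frame(matrix(22, 8, 8))
  st <- frame_stats(uni)
  expect_equal(st$max_c, 22)
  expect_equal(st$mean_c, 22)

  g <- matrix(22, 8, 8); g[3, 5] <- 80
  st2 <- frame_stats(thermal_frame(g))
  expect_equal(st2$max_c, 80)
  expect_equal(c(st2$argmax_row, st2$argmax_col), c(2L, 4L))

  # named regions vs direct summation
  mask_seat <- matrix(FALSE, 8, 8); mask_seat[1:4, 1:4] <- TRUE
  set.seed(13)
  gr <- matrix(runif(64, 20, 30), 8, 8)
  st3 <- frame_stats(thermal_frame(gr), regions = list(seat = mask_seat))
  expect_equal(st3$mean_c[st3$region == "seat"],
               sum(gr[mask_seat]) / sum(mask_seat), tolerance = 1e-9)

  expect_error(frame_stats(thermal_frame(gr), regions = list(bad = 65)),
               "outside")
  expect_error(thermal_frame(matrix(22, 4, 4)), "64|8x8")
  expect_error(thermal_frame(matrix(2000, 8, 8)), "range")
})

test_that("temporal gradient is an exact least-squares slope", {
  mkframes <- function(slopes, n = 10, dt = 0.5, base = 22) {
    lapply(seq_len(n), function(k) {
      thermal_frame(base + slopes * (k - 1) * dt, time_s = (k - 1) * dt)
    })
  }
  const <- mkframes(matrix(0, 8, 8))
  expect_true(all(temporal_gradient(const) == 0))

  s <- matrix(0, 8, 8); s[2, 2] <- 0.5
  ramp <- mkframes(s)
  grad <- temporal_gradient(ramp)
  expect_equal(grad[2, 2], 0.5, tolerance = 1e-6)
  expect_equal(grad[1, 1], 0, tolerance = 1e-9)

  # linearity in the frame values
  s2 <- matrix(0, 8, 8); s2[5, 7] <- 0.2
  f1 <- mkframes(s); f2 <- mkframes(s2)
  fsum <- lapply(seq_along(f1), function(k) {
    thermal_frame(f1[[k]]$temps + f2[[k]]$temps - 22, time_s = f1[[k]]$time_s)
  })
  expect_equal(temporal_gradient(fsum),
               temporal_gradient(f1) + temporal_gradient(f2),
               tolerance = 1e-9)

  bad <- const
  bad[[2]]$time_s <- -1
  expect_error(temporal_gradient(bad), "increasing")
})

test_that("thermal classification: regimes, the 40 degC rule and precedence", {
  amb <- gen_thermal_sequence("ambient", 50, fps = 10, seed = 5)
  expect_equal(classify_thermal(amb)$label, "ambient")

  # a region reaching 41 degC is an overheat
  hot <- lapply(1:5, function(k) {
    g <- matrix(22, 8, 8); g[4, 4] <- 41
    thermal_frame(g, time_s = (k - 1) * 0.5)
  })
  res <- classify_thermal(hot)
  expect_equal(res$label, "overheat")
  expect_equal(unlist(res$trigger_pixels), c(row = 3L, col = 3L))

  fl <- gen_thermal_sequence("flame", 50, fps = 10, seed = 5)
  res_fl <- classify_thermal(fl)
  expect_equal(res_fl$label, "flame")
  expect_gt(nrow(res_fl$trigger_pixels), 0)
  # the generator's hot core is among the trigger pixels
  hot_px <- which(vapply(seq_len(64), function(i) {
    max(vapply(fl, function(f) f$temps[[i]], numeric(1))) > 80
  }, logical(1)))
  trig_lin <- res_fl$trigger_pixels$row + 1L + 8L * res_fl$trigger_pixels$col
  expect_true(all(hot_px %in% trig_lin))

  wm <- gen_thermal_sequence("warming", 240, fps = 10, seed = 5)
  expect_equal(classify_thermal(wm, thermal_config(gradient_window = 240))$label,
               "warming")
})

test_that("heating a pixel never downgrades severity; labels are permutation-stable", {
  set.seed(99)
  for (trial in 1:200) {
    frames <- gen_thermal_sequence(sample(c("ambient", "warming", "flame"), 1),
                                   n_frames = 12, fps = 10,
                                   seed = sample.int(1e6, 1))
    base_label <- classify_thermal(frames)$label
    # heat one pixel's whole trajectory by a positive offset
    px <- sample.int(64, 1)
    delta <- runif(1, 0.5, 30)
    heated <- lapply(frames, function(f) {
      g <- f$temps
      g[[px]] <- min(g[[px]] + delta, 1000)
      thermal_frame(g, f$time_s)
    })
    expect_gte(thermal_severity(classify_thermal(heated)$label),
               thermal_severity(base_label))
  }

  # permuting pixel positions identically in every frame preserves labels
  perm <- sample.int(8)
  for (regime in c("ambient", "flame")) {
    frames <- gen_thermal_sequence(regime, 20, fps = 10, seed = 17)
    permuted <- lapply(frames, function(f) {
      thermal_frame(f$temps[perm, perm], f$time_s)
    })
    expect_equal(classify_thermal(permuted)$label,
                 classify_thermal(frames)$label)
  }
})
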