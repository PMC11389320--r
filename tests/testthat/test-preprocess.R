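test_that("raw CSV round-trips bitwise and rejects malformed input", {
  p <- noiseless_participant()
  bout <- simulate_bout(p, "walking", 3.3, 1, 10, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(bout$recording, f)
  rec2 <- read_raw_csv(f)
  expect_equal(rec2$acc, bout$recording$acc, tolerance = 1e-12)
  expect_equal(rec2$sample_rate, 100, tolerance = 1e-6)

  # small well-formed file parses to its own length
  writeLines(c("timestamp_s,x_g,y_g,z_g", "0,0,0,-1", "0.01,0,0,-1",
               "0.02,0,0,-1", "0.03,0,0,-1"), f)
  expect_identical(nrow(read_raw_csv(f)$acc), 4L)

  # backwards timestamp rejected with the offending line named
  writeLines(c("timestamp_s,x_g,y_g,z_g", "0,0,0,-1", "0.02,0,0,-1",
               "0.01,0,0,-1"), f)
  expect_error(read_raw_csv(f), "non-monotone")
  writeLines(c("timestamp_s,x_g", "0,0"), f)
  expect_error(read_raw_csv(f), "missing columns")
  writeLines("timestamp_s,x_g,y_g,z_g", f)
  expect_error(read_raw_csv(f), "empty")
})

test_that("resampling is exact on uniform grids and linear signals", {
  p <- noiseless_participant()
  bout <- simulate_bout(p, "sitting", duration_s = 10, seed = 2)
  out <- resample_uniform(bout$recording, 100)
  expect_equal(out$acc, bout$recording$acc, tolerance = 1e-12)

  # 50 Hz ramp -> 100 Hz ramp with identical slope
  t50 <- seq(0, 2, by = 1 / 50)
  ramp <- raw_recording(cbind(0.1 * t50, 0, 0), 50)
  up <- resample_uniform(ramp, 100)
  expect_equal(up$sample_rate, 100)
  slope <- diff(up$acc[, 1]) * 100
  expect_equal(max(abs(slope - 0.1)), 0, tolerance = 1e-9)

  # off-grid sinusoid: linear interpolation error small vs closed form
  fs0 <- 97.3
  t0 <- seq(0, 5, by = 1 / fs0)
  rec <- raw_recording(cbind(sin(2 * pi * 2 * t0), 0, 0), fs0)
  rs <- resample_uniform(rec, 100, times = t0)
  t1 <- rs$start_time + (seq_len(nrow(rs$acc)) - 1) / 100
  expect_lt(max(abs(rs$acc[, 1] - sin(2 * pi * 2 * t1))), 0.01)

  expect_error(resample_uniform(raw_recording(matrix(0, 1, 3), 100)), "2 samples")
})

test_that("zero-phase Butterworth filtering matches the analytic response", {
  fs <- 100
  # DC gain 1
  const <- matrix(0.7, 2000, 1)
  y <- lowpass_butterworth(const[, 1], 8, 20, fs)
  expect_equal(max(abs(y - 0.7)), 0, tolerance = 1e-9)
  # |H|^2 at the cutoff is 1/2 for the forward-backward pass
  t <- seq(0, 20, by = 1 / fs)
  x20 <- sin(2 * pi * 20 * t)
  y20 <- lowpass_butterworth(x20, 8, 20, fs)
  expect_equal(mid_rms(y20) / mid_rms(x20), 0.5, tolerance = 0.02)
  # 40 Hz is crushed: (40/20)^(-16) per the squared response
  x40 <- sin(2 * pi * 40 * t)
  y40 <- lowpass_butterworth(x40, 8, 20, fs)
  expect_lt(mid_rms(y40) / mid_rms(x40), 0.001)
  # applying twice ~ squared response (checked at the cutoff)
  y20b <- lowpass_butterworth(y20, 8, 20, fs)
  expect_equal(mid_rms(y20b) / mid_rms(y20), 0.5, tolerance = 0.02 * 2)
  expect_error(lowpass_butterworth(x20, 8, 60, fs), "Nyquist")
})

test_that("autocalibration recovers known gain/offset distortions", {
  # six cube orientations, distorted by known gain and offset
  gain <- c(1.05, 0.97, 1.02)
  offset <- c(0.02, -0.03, 0.01)
  oris <- rbind(diag(3), -diag(3))
  set.seed(42)
  # 10-s segments aligned to the static-window grid
  acc <- do.call(rbind, lapply(seq_len(6), function(i) {
    true <- matrix(rep(oris[i, ], each = 1000), 1000, 3)
    meas <- sweep(sweep(true, 2, offset, `-`), 2, gain, `/`)
    meas + matrix(rnorm(3000, 0, 0.003), 1000, 3)
  }))
  rec <- raw_recording(acc, 100)
  out <- autocalibrate(rec)
  expect_false(out$params$failed)
  expect_lt(max(abs(out$params$gain - gain) / gain), 0.01)
  expect_lt(max(abs(out$params$offset - offset)), 0.005)
  # the calibrated static magnitudes sit on the unit sphere
  nrm <- sqrt(rowSums(out$recording$acc^2))
  expect_lt(abs(mean(nrm) - 1), 0.005)
})

test_that("autocalibration is a flagged no-op on degenerate input", {
  # perfectly calibrated data recovers the identity
  set.seed(7)
  oris <- rbind(diag(3), -diag(3))
  acc <- do.call(rbind, lapply(seq_len(6), function(i) {
    matrix(rep(oris[i, ], each = 1000), 1000, 3) +
      matrix(rnorm(3000, 0, 0.003), 1000, 3)
  }))
  out <- autocalibrate(raw_recording(acc, 100))
  expect_lt(max(abs(out$params$gain - 1)), 1e-3)
  expect_lt(max(abs(out$params$offset)), 1e-3)

  # pure walking (no static windows) -> identity + warning
  p <- synthetic_participant("W", 3)
  bout <- simulate_bout(p, "walking", 4.1, 1, 30, seed = 5)
  expect_warning(out2 <- autocalibrate(bout$recording), "insufficient static")
  expect_true(out2$params$failed)
  expect_identical(out2$params$gain, c(1, 1, 1))
  expect_identical(out2$recording$acc, bout$recording$acc)
})

test_that("cube-routine references solve the two-point linear system", {
  mk <- function(v) static_recording(v, duration_s = 6)
  segs <- list(mk(c(1, 0, 0)), mk(c(-1, 0, 0)), mk(c(0, 1, 0)),
               mk(c(0, -1, 0)), mk(c(0, 0, 1)), mk(c(0, 0, -1)))
  cal <- estimate_axis_references(segs)
  expect_equal(cal$gain, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(cal$offset, c(0, 0, 0), tolerance = 1e-12)

  # x readings +1.05 / -0.95 -> gain 1, offset -0.05 (hand solution)
  segs2 <- segs
  segs2[[1]] <- mk(c(1.05, 0, 0))
  segs2[[2]] <- mk(c(-0.95, 0, 0))
  cal2 <- estimate_axis_references(segs2)
  expect_equal(cal2$gain[1], 1, tolerance = 1e-12)
  expect_equal(cal2$offset[1], -0.05, tolerance = 1e-12)

  expect_error(estimate_axis_references(segs[1:5]), "six")
  segs3 <- segs
  segs3[[1]] <- mk(c(0.3, 0, 0))
  expect_error(estimate_axis_references(segs3), "mis-oriented")
})

test_that("epoching discards the tail and applies the full-coverage label rule", {
  rec <- raw_recording(matrix(rnorm(1000 * 3, 0, 0.01), 1000, 3), 100)
  ep <- make_epochs(rec)
  expect_identical(length(ep), 2L)

  p <- noiseless_participant()
  bout <- simulate_bout(p, "walking", 3.3, 1, 360, seed = 1)
  ep2 <- make_epochs(bout$recording,
                     data.frame(start_s = 0, end_s = 360, activity = "walking"))
  expect_identical(length(ep2), 90L)
  expect_true(all(ep2$info$true_label == "walking"))

  # epoch spanning a label boundary stays unlabelled
  labs <- data.frame(start_s = c(0, 6), end_s = c(6, 360),
                     activity = c("sitting", "standing"))
  ep3 <- make_epochs(bout$recording, labs)
  expect_identical(ep3$info$true_label[1], "sitting")
  expect_true(is.na(ep3$info$true_label[2]))   # covers [4, 8), split at 6
  expect_identical(ep3$info$true_label[3], "standing")

  short <- raw_recording(matrix(0, 100, 3), 100)
  expect_warning(ep4 <- make_epochs(short), "shorter")
  expect_identical(length(ep4), 0L)
})

test_that("epoch windows concatenate back to the input minus the tail", {
  rec <- raw_recording(matrix(rnorm(1000 * 3, 0, 0.01), 1000, 3), 100)
  ep <- make_epochs(rec)
  flat <- do.call(rbind, lapply(seq_len(length(ep)), function(i) ep$windows[i, , ]))
  expect_equal(flat, unname(rec$acc[1:800, ]), tolerance = 1e-15)
})
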