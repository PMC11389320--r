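test_that("noiseless static bouts have unit vector magnitude and no strides", {
  p <- noiseless_participant()
  for (act in c("sitting", "standing")) {
    bout <- simulate_bout(p, act, duration_s = 60, seed = 3)
    nrm <- sqrt(rowSums(bout$recording$acc^2))
    expect_equal(max(abs(nrm - 1)), 0, tolerance = 1e-12)
    expect_identical(bout$true_stride_count, 0L)
    expect_gt(bout$true_ee, 0)
  }
  # orientation convention: standing loads x, sitting loads z
  sit <- simulate_bout(p, "sitting", duration_s = 20, seed = 1)
  sta <- simulate_bout(p, "standing", duration_s = 20, seed = 1)
  expect_lt(max(abs(sit$recording$acc[, 1])), 0.1)
  expect_equal(mean(sta$recording$acc[, 1]), -1, tolerance = 1e-6)
})

test_that("stride counts follow the configured stride frequency", {
  p <- noiseless_participant()
  bout <- simulate_bout(p, "walking", 4.1, 1, 360, seed = 5)
  expect_identical(bout$true_stride_count,
                   round(bout$stride_freq_hz * 360))
  # analytic example: freq 0.9 Hz over 360 s -> 324 strides
  p2 <- p
  p2$freq_factor[["walking"]] <- 0.9 / (0.70 + 0.35 * 0.5)
  b2 <- simulate_bout(p2, "walking", 3.3, 1, 360, seed = 5)
  expect_equal(b2$stride_freq_hz, 0.9, tolerance = 1e-12)
  expect_identical(b2$true_stride_count, 324)
})

test_that("bout simulation is deterministic given the seed", {
  p <- synthetic_participant("P01", 7)
  a <- simulate_bout(p, "running", 9.5, 1, 20, seed = 99)
  b <- simulate_bout(p, "running", 9.5, 1, 20, seed = 99)
  expect_identical(a$recording$acc, b$recording$acc)
  c <- simulate_bout(p, "running", 9.5, 1, 20, seed = 100)
  expect_false(identical(a$recording$acc, c$recording$acc))
})

test_that("invalid bout requests are rejected", {
  p <- noiseless_participant()
  expect_error(simulate_bout(p, "swimming", duration_s = 60), "unknown activity")
  expect_error(simulate_bout(p, "walking", 3.3, 1, -5), "positive")
  expect_error(simulate_bout(p, "walking", 3.3, 1, 4), "at least 8")
})

test_that("gait waveforms have their spectral peak at the stride frequency", {
  p <- noiseless_participant()
  cases <- list(c("walking", 3.7), c("running", 9.0), c("cycling", 90))
  for (cs in cases) {
    bout <- simulate_bout(p, cs[1], as.numeric(cs[2]), 1, 120, seed = 4)
    axis <- default_config()$strides$stride_axis[[cs[1]]]
    x <- bout$recording$acc[, axis]
    sp <- stats::spec.pgram(x - mean(x), plot = FALSE, taper = 0)
    fpk <- sp$freq[which.max(sp$spec)] * 100   # per-sample freq -> Hz
    expect_lt(abs(fpk - bout$stride_freq_hz) / bout$stride_freq_hz, 0.05)
  }
})

test_that("metabolic ground truth is strictly monotone and positive", {
  # hand evaluation of the configured equations:
  # walking 3.7 km/h @ 1%: VO2 = 3.5 + 0.1*61.667 + 1.8*61.667*0.01
  s <- 3.7 * 1000 / 60
  expect_equal(metabolic_ground_truth("walking", 3.7, 1),
               (3.5 + 0.1 * s + 1.8 * s * 0.01) * 5 / 1000, tolerance = 1e-12)
  # cycling 90 vs 120 W at 70 kg: hand values of the work-rate equation
  ee90 <- (7 + 1.8 * 6.12 * 90 / 70) * 5 / 1000
  ee120 <- (7 + 1.8 * 6.12 * 120 / 70) * 5 / 1000
  expect_equal(metabolic_ground_truth("cycling", 90, 0, 70), ee90,
               tolerance = 1e-12)
  expect_equal(metabolic_ground_truth("cycling", 120, 0, 70), ee120,
               tolerance = 1e-12)
  expect_gt(ee120, ee90)
  # zero speed / zero grade leaves the resting component (> 0)
  expect_gt(suppressWarnings(metabolic_ground_truth("walking", 0, 0)), 0)
  # monotone in speed, grade, and watts
  expect_gt(metabolic_ground_truth("walking", 4.5, 1),
            metabolic_ground_truth("walking", 3.7, 1))
  expect_gt(metabolic_ground_truth("running", 9.5, 6),
            metabolic_ground_truth("running", 9.5, 1))
  expect_error(metabolic_ground_truth("cycling", 90, 0, -1), "positive")
  expect_warning(metabolic_ground_truth("walking", 6.5, 1), "extrapolating")
})

test_that("simulated breaths invert through the Weir equation", {
  # noiseless: every breath reproduces the target exactly
  br <- simulate_breaths(5.2, rer = 0.9, duration_s = 300, noise_cv = 0, seed = 8)
  ee <- weir_energy_expenditure(br$vo2_lmin, br$vco2_lmin)
  expect_equal(max(abs(ee - 5.2)), 0, tolerance = 1e-9)
  # rer = 1 makes VCO2 equal VO2
  br1 <- simulate_breaths(5.2, rer = 1, duration_s = 60, noise_cv = 0, seed = 8)
  expect_equal(br1$vo2_lmin, br1$vco2_lmin, tolerance = 1e-12)
  # 5% noise over 300 s: mean within 2%
  brn <- simulate_breaths(5.2, rer = 0.9, duration_s = 300, noise_cv = 0.05,
                          seed = 8)
  expect_lt(abs(mean(weir_energy_expenditure(brn$vo2_lmin, brn$vco2_lmin)) - 5.2) / 5.2,
            0.02)
  expect_error(simulate_breaths(5, rer = 1.5, duration_s = 60), "rer")
  expect_error(simulate_breaths(5, rer = 0.9, duration_s = 60, noise_cv = -1),
               "noise_cv")
})

test_that("the protocol has the published condition structure", {
  conds <- protocol_conditions()
  tab <- table(conds$activity)
  expect_identical(as.integer(tab[c("sitting", "standing", "walking",
                                    "running", "cycling")]),
                   c(1L, 1L, 9L, 9L, 8L))
  expect_true(all(conds$duration_s == 360))
  # every cycling power in the published ladder
  expect_setequal(conds$intensity[conds$activity == "cycling"],
                  c(30, 50, 60, 75, 90, 100, 120, 150))
})

test_that("simulate_protocol is reproducible and writes readable fixtures", {
  short_cfg <- default_config(synth = list(bout_duration_s = 8))
  a <- simulate_protocol(1, seed = 21, config = short_cfg)
  b <- simulate_protocol(1, seed = 21, config = short_cfg)
  expect_identical(a$bouts[["P01"]][[3]]$recording$acc,
                   b$bouts[["P01"]][[3]]$recording$acc)
  expect_length(a$bouts[["P01"]], 28)

  out <- withr::local_tempdir()
  simulate_protocol(1, seed = 21, out_dir = out, config = short_cfg)
  rec <- read_raw_csv(file.path(out, "P01_acc.csv"))
  expect_s3_class(rec, "raw_recording")
  labs <- utils::read.csv(file.path(out, "P01_labels.csv"))
  expect_identical(nrow(labs), 28L)
  br <- read_breath_csv(file.path(out, "P01_breaths.csv"))
  expect_true(all(br$vo2_lmin > 0))
})

test_that("generated accelerations are finite and within the device range", {
  p <- synthetic_participant("P05", 13)
  # top-of-protocol intensities (km/h, km/h, W)
  tops <- c(walking = 4.5, running = 10.5, cycling = 150)
  for (act in names(tops)) {
    bout <- simulate_bout(p, act, tops[[act]], 6, 20, seed = 3)
    expect_true(all(is.finite(bout$recording$acc)))
    expect_lte(max(abs(bout$recording$acc)), 8)
  }
})
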