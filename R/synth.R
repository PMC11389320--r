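# Synthetic thigh-accelerometer generator.
#
# Orientation convention (used by the generator and reused by tests):
#   standing        -> gravity on x: (-1, 0, 0)
#   sitting         -> thigh horizontal, gravity on z: (0, 0, -1)
#   walking/running -> upright baseline (-1, 0, 0), stride axis z (walking)
#                      or x (running)
#   cycling         -> thigh pitched ~44 deg: (-cos44, 0, -sin44), stride
#                      axis x
GRAVITY_BY_ACTIVITY <- list(
  sitting  = c(0, 0, -1),
  standing = c(-1, 0, 0),
  walking  = c(-1, 0, 0),
  running  = c(-1, 0, 0),
  cycling  = c(-cos(44 * pi / 180), 0, -sin(44 * pi / 180))
)

# protocol intensity ranges used to normalise intensity to [0, 1]
INTENSITY_RANGE <- list(
  walking = c(2.1, 4.5),    # km/h
  running = c(7.5, 10.5),   # km/h
  cycling = c(30, 150)      # W
)

intensity_norm <- function(activity, intensity) {
  r <- INTENSITY_RANGE[[activity]]
  (intensity - r[1]) / (r[2] - r[1])
}

#' Create a synthetic participant
#'
#' Draws per-participant simulator parameters: body mass and height,
#' activity-specific stride-frequency and amplitude factors, harmonic
#' waveform weights and phases, sensor noise, and a preferred cycling
#' cadence (60-80 rpm). All draws are deterministic given `seed`.
#'
#' @param id Participant identifier (string).
#' @param seed Integer seed.
#' @param config Pipeline configuration (only `$synth` is used).
#' @return An object of class `"synthetic_participant"`.
#' @export
synthetic_participant <- function(id, seed, config = default_config()) {
  sc <- config$synth
  with_seed(seed, {
    mass <- min(max(stats::rnorm(1, 72, 12), sc$mass_range[1]), sc$mass_range[2])
    height <- min(max(stats::rnorm(1, 172, 9), sc$height_range[1]), sc$height_range[2])
    p <- list(
      id = as.character(id),
      mass_kg = mass,
      height_cm = height,
      # multiplicative stride-frequency factors (individual cadence)
      freq_factor = c(walking = stats::runif(1, 0.92, 1.08),
                      running = stats::runif(1, 0.92, 1.08)),
      rpm = stats::runif(1, 60, 80),
      # amplitude factor (individual acceleration magnitude)
      amp_factor = stats::runif(1, 0.85, 1.15),
      # fixed upper-harmonic weights and phases per gait activity
      harmonics = lapply(stats::setNames(nm = c("walking", "running", "cycling")),
                         function(a) list(
                           w3 = stats::runif(1, 0.05, 0.12),
                           w4 = stats::runif(1, 0.02, 0.06),
                           phase = stats::runif(4, 0, 2 * pi),
                           phase_other = stats::runif(2, 0, 2 * pi)
                         )),
      noise_sd = stats::runif(1, sc$noise_sd_range[1], sc$noise_sd_range[2]),
      rer_base = stats::runif(1, 0.76, 0.82)
    )
    structure(p, class = "synthetic_participant")
  })
}

#' @export
print.synthetic_participant <- function(x, ...) {
  cat(sprintf("<participant %s> mass %.1f kg, height %.0f cm, rpm %.0f, noise %.3f g\n",
              x$id, x$mass_kg, x$height_cm, x$rpm, x$noise_sd))
  invisible(x)
}

#' Stride frequency for an activity condition
#'
#' Walking and running stride frequencies increase linearly with speed
#' across the protocol range (walking 0.70-1.05 Hz, running 1.30-1.65 Hz
#' before the individual cadence factor) and are clipped to the
#' plausibility bands (walking 0.6-1.2 Hz, running 1.2-1.8 Hz). Cycling
#' "stride" frequency is the pedal cadence, rpm / 60.
#'
#' @param participant A [synthetic_participant()].
#' @param activity One of walking/running/cycling.
#' @param intensity Speed (km/h) or power (W).
#' @return Stride frequency in Hz.
#' @export
stride_frequency <- function(participant, activity, intensity) {
  u <- intensity_norm(activity, intensity)
  f <- switch(activity,
    walking = (0.70 + 0.35 * u) * participant$freq_factor[["walking"]],
    running = (1.30 + 0.35 * u) * participant$freq_factor[["running"]],
    cycling = participant$rpm / 60,
    stop("no stride frequency for activity: ", activity)
  )
  bounds <- switch(activity, walking = c(0.6, 1.2), running = c(1.2, 1.8),
                   cycling = c(1.0, 1.4))
  min(max(f, bounds[1]), bounds[2])
}

# stride-axis peak amplitude (g) for a gait bout
stride_amplitude <- function(participant, activity, intensity) {
  u <- intensity_norm(activity, intensity)
  base <- switch(activity,
    walking = 0.25 + 0.45 * u,
    running = 0.80 + 0.80 * u,
    cycling = 0.35 + 0.25 * u
  )
  base * participant$amp_factor
}

#' Simulate one activity bout
#'
#' Generates a 100 Hz triaxial recording for one protocol condition.
#' Static bouts place the gravity vector per the orientation convention
#' plus sensor noise and a small postural sway proportional to the noise
#' level (so noiseless static bouts have vector magnitude exactly 1 g).
#' Gait bouts put a multi-harmonic stride waveform on the designated
#' stride axis (z for walking, x for running/cycling) with amplitude
#' increasing in intensity; treadmill incline above the 1% default shifts
#' the relative weight and phase of the second harmonic. The remaining
#' axes carry correlated lower-amplitude periodicity plus the gravity
#' projection. Deterministic given `seed`.
#'
#' @param participant A [synthetic_participant()].
#' @param activity One of sitting/standing/walking/running/cycling.
#' @param intensity Speed (km/h) or power (W); `NA` for static bouts.
#' @param incline_pct Treadmill grade in percent (0 for cycling/static).
#' @param duration_s Bout duration in seconds (>= 8, two epochs).
#' @param seed Integer seed for the sensor noise.
#' @param config Pipeline configuration.
#' @return An object of class `"synthetic_bout"` with fields `recording`
#'   ([raw_recording()]), `true_ee` (kcal/kg/min), `true_stride_count`,
#'   `stride_freq_hz`, and the condition descriptors.
#' @export
simulate_bout <- function(participant, activity, intensity = NA,
                          incline_pct = 0, duration_s = 360, seed = 1L,
                          config = default_config()) {
  if (!activity %in% activity_levels()) {
    stop("unknown activity: ", activity)
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration must be positive")
  }
  if (duration_s < 8) stop("duration must be at least 8 s (two epochs)")
  fs <- config$sample_rate_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  gait <- activity %in% c("walking", "running", "cycling")
  acc <- matrix(0, n, 3)
  f <- 0
  if (!gait) {
    g <- GRAVITY_BY_ACTIVITY[[activity]]
    acc <- matrix(rep(g, each = n), n, 3)
    # postural sway, scaled by noise level so the noiseless case is exact
    sway <- 0.5 * participant$noise_sd
    acc[, 1] <- acc[, 1] + sway * sin(2 * pi * 0.25 * t)
    acc[, 3] <- acc[, 3] + sway * sin(2 * pi * 0.18 * t + 1.1)
  } else {
    if (!is.finite(intensity)) stop("gait bouts require a numeric intensity")
    f <- stride_frequency(participant, activity, intensity)
    A <- stride_amplitude(participant, activity, intensity)
    u <- intensity_norm(activity, intensity)
    h <- participant$harmonics[[activity]]
    grade_excess <- if (activity == "cycling") 0 else max(incline_pct - 1, 0) / 5
    # harmonic weights: the 2nd harmonic encodes intensity and incline.
    # Upper harmonics are kept weak enough that the 5 Hz-filtered stride
    # axis retains a single dominant peak per cycle, as real thigh
    # acceleration does (the premise of peak-based stride segmentation).
    w <- c(1,
           0.10 + 0.12 * min(max(u, 0), 1.2) + 0.06 * grade_excess,
           h$w3, h$w4)
    ph <- h$phase
    ph[2] <- ph[2] + 0.6 * grade_excess
    s <- rowSums(vapply(1:4, function(k) {
      w[k] * sin(2 * pi * k * f * t + ph[k])
    }, numeric(n)))
    s <- A * s / sqrt(sum(w^2) / 2)   # normalise to RMS amplitude A/sqrt(2)
    g <- GRAVITY_BY_ACTIVITY[[activity]]
    axis <- config$strides$stride_axis[[activity]]
    acc <- matrix(rep(g, each = n), n, 3)
    acc[, axis] <- acc[, axis] + s
    others <- setdiff(1:3, axis)
    acc[, others[1]] <- acc[, others[1]] +
      0.35 * A * sin(2 * pi * f * t + h$phase_other[1])
    acc[, others[2]] <- acc[, others[2]] +
      0.20 * A * sin(2 * pi * f * t + h$phase_other[2])
  }
  if (participant$noise_sd > 0) {
    acc <- acc + with_seed(seed, matrix(stats::rnorm(n * 3, 0, participant$noise_sd), n, 3))
  }
  if (max(abs(acc)) > 8) {
    warning("synthetic acceleration exceeded +/-8 g and was clipped")
    acc[acc > 8] <- 8; acc[acc < -8] <- -8
  }
  structure(list(
    participant_id = participant$id,
    mass_kg = participant$mass_kg,
    activity = activity,
    intensity = intensity,
    incline_pct = incline_pct,
    duration_s = duration_s,
    recording = raw_recording(acc, fs),
    stride_freq_hz = f,
    true_stride_count = if (gait) round(f * duration_s) else 0L,
    true_ee = metabolic_ground_truth(activity, intensity, incline_pct,
                                     participant$mass_kg, config = config)
  ), class = "synthetic_bout")
}

#' @export
print.synthetic_bout <- function(x, ...) {
  cat(sprintf("<bout %s> %s %s, %.0f s, true EE %.4f kcal/kg/min, %d strides\n",
              x$participant_id, x$activity,
              if (is.na(x$intensity)) "" else format(x$intensity),
              x$duration_s, x$true_ee, x$true_stride_count))
  invisible(x)
}

#' Metabolic ground-truth energy expenditure
#'
#' Standard metabolic prediction equations, fixed in the configuration:
#' walking/running use speed- and grade-linear oxygen-cost models
#' (VO2 = rest + a*S + b*S*G, S in m/min, G fractional grade), cycling
#' uses a work-rate-linear model (rest + unloaded + 1.8 * kg-m/min / mass),
#' sitting/standing use MET constants. VO2 is converted at 5 kcal per
#' litre O2 and expressed per kilogram.
#'
#' @param activity Activity label.
#' @param intensity Speed in km/h (walking/running) or power in W
#'   (cycling); ignored for sitting/standing.
#' @param incline_pct Treadmill grade in percent.
#' @param mass_kg Body mass (> 0); only cycling EE per kg depends on it.
#' @param config Pipeline configuration (`$metabolic` section).
#' @return Energy expenditure in kcal/kg/min (> 0, monotone increasing in
#'   speed, grade and power).
#' @export
metabolic_ground_truth <- function(activity, intensity = NA, incline_pct = 0,
                                   mass_kg = 70, config = default_config()) {
  if (!is.numeric(mass_kg) || mass_kg <= 0) stop("mass must be positive")
  mc <- config$metabolic
  gait <- activity %in% c("walking", "running", "cycling")
  if (gait) {
    r <- INTENSITY_RANGE[[activity]]
    if (is.finite(intensity) && (intensity < r[1] || intensity > r[2]) &&
        intensity != 0) {
      warning(activity, " intensity ", intensity,
              " outside the protocol range [", r[1], ", ", r[2],
              "]; extrapolating")
    }
  }
  vo2 <- switch(activity,
    sitting = mc$rest_vo2 * mc$sitting_mets,
    standing = mc$rest_vo2 * mc$standing_mets,
    walking = {
      S <- intensity * 1000 / 60; G <- incline_pct / 100
      mc$rest_vo2 + mc$walk_speed_coef * S + mc$walk_grade_coef * S * G
    },
    running = {
      S <- intensity * 1000 / 60; G <- incline_pct / 100
      mc$rest_vo2 + mc$run_speed_coef * S + mc$run_grade_coef * S * G
    },
    cycling = {
      mc$rest_vo2 + mc$cycle_unloaded_vo2 +
        mc$cycle_work_coef * (mc$kgm_per_watt_min * intensity) / mass_kg
    },
    stop("unknown activity: ", activity)
  )
  vo2 * mc$kcal_per_l_o2 / 1000
}

#' Simulate breath-by-breath gas exchange
#'
#' Breath times follow gamma-distributed inter-breath intervals at a rate
#' drawn between 12 and 30 breaths/min. Per-breath VO2 carries
#' multiplicative noise with coefficient of variation `noise_cv`;
#' VCO2 = rer * VO2 exactly, and the noiseless Weir conversion of every
#' breath equals `true_ee_kcal_min`. Deterministic given `seed`.
#'
#' @param true_ee_kcal_min Target absolute energy expenditure (kcal/min).
#' @param rer Respiratory exchange ratio, in `[0.7, 1.2]`.
#' @param duration_s Duration covered by the breath record.
#' @param noise_cv Fractional per-breath noise (>= 0).
#' @param seed Integer seed.
#' @param config Pipeline configuration (`$calorimetry` Weir coefficients).
#' @return Data frame with columns `time_s`, `vo2_lmin`, `vco2_lmin`.
#' @export
simulate_breaths <- function(true_ee_kcal_min, rer = 0.85, duration_s = 360,
                             noise_cv = 0, seed = 1L,
                             config = default_config()) {
  if (rer < 0.7 || rer > 1.2) stop("rer must lie in [0.7, 1.2]")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  cc <- config$calorimetry
  with_seed(seed, {
    rate <- stats::runif(1, 12, 30)            # breaths per minute
    mean_ibi <- 60 / rate
    n_max <- ceiling(duration_s / mean_ibi * 2) + 20
    ibi <- stats::rgamma(n_max, shape = 25, scale = mean_ibi / 25)
    times <- cumsum(ibi)
    times <- times[times < duration_s]
    n <- length(times)
    vo2 <- true_ee_kcal_min / (cc$weir_vo2 + cc$weir_vco2 * rer)
    fac <- if (noise_cv > 0) pmax(1 + stats::rnorm(n, 0, noise_cv), 0.2) else rep(1, n)
    data.frame(time_s = times, vo2_lmin = vo2 * fac, vco2_lmin = rer * vo2 * fac)
  })
}

#' The laboratory activity protocol
#'
#' One row per activity condition, merging the training and validation
#' arms: sitting, standing, nine walking conditions (2.1-4.5 km/h at 1%
#' plus 3.7 and 3.3 km/h at 6%), nine running conditions (7.5-10.5 km/h at
#' 1% plus 9.5 and 8 km/h at 6%), and eight cycling power levels
#' (30-150 W). Every condition lasts 6 minutes.
#'
#' @param config Pipeline configuration.
#' @return Data frame with columns `activity`, `intensity`, `incline_pct`,
#'   `duration_s`.
#' @export
protocol_conditions <- function(config = default_config()) {
  d <- config$synth$bout_duration_s
  rbind(
    data.frame(activity = c("sitting", "standing"), intensity = NA_real_,
               incline_pct = 0, duration_s = d),
    data.frame(activity = "walking",
               intensity = c(2.1, 2.5, 2.9, 3.3, 3.7, 4.1, 4.5, 3.7, 3.3),
               incline_pct = c(rep(1, 7), 6, 6), duration_s = d),
    data.frame(activity = "running",
               intensity = c(7.5, 8, 8.5, 9, 9.5, 10, 10.5, 9.5, 8),
               incline_pct = c(rep(1, 7), 6, 6), duration_s = d),
    data.frame(activity = "cycling",
               intensity = c(30, 50, 60, 75, 90, 100, 120, 150),
               incline_pct = 0, duration_s = d)
  )
}

# respiratory exchange ratio for a condition (rises with intensity)
condition_rer <- function(participant, activity, intensity) {
  u <- if (activity %in% names(INTENSITY_RANGE)) {
    min(max(intensity_norm(activity, intensity), 0), 1.2)
  } else 0
  min(max(participant$rer_base + 0.20 * u, 0.7), 1.1)
}

#' Simulate the full activity protocol
#'
#' Generates, for each participant, one bout per protocol condition with
#' its recording, activity label, ground-truth EE and simulated breath
#' record. Optionally writes the three CSV streams per participant
#' (concatenated raw acceleration, breaths, labels). Deterministic given
#' `seed`. Intended for modest `n_participants`; recordings are held in
#' memory.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer root seed.
#' @param out_dir Optional directory for CSV fixtures.
#' @param config Pipeline configuration.
#' @return A list with `participants` and `bouts` (list of lists of
#'   `synthetic_bout`, each with a `$breaths` data frame attached).
#' @export
simulate_protocol <- function(n_participants, seed = 1L, out_dir = NULL,
                              config = default_config()) {
  stopifnot(n_participants >= 1)
  seeds <- derive_seeds(seed, n_participants)
  conds <- protocol_conditions(config)
  participants <- list()
  bouts <- list()
  for (i in seq_len(n_participants)) {
    p <- synthetic_participant(sprintf("P%02d", i), seeds[i], config)
    bseeds <- derive_seeds(seeds[i], 2 * nrow(conds))
    pb <- vector("list", nrow(conds))
    for (b in seq_len(nrow(conds))) {
      cond <- conds[b, ]
      bout <- simulate_bout(p, cond$activity, cond$intensity,
                            cond$incline_pct, cond$duration_s,
                            seed = bseeds[b], config = config)
      rer <- condition_rer(p, cond$activity, cond$intensity)
      bout$breaths <- simulate_breaths(
        bout$true_ee * p$mass_kg, rer, cond$duration_s,
        noise_cv = config$synth$breath_noise_cv,
        seed = bseeds[nrow(conds) + b], config = config
      )
      pb[[b]] <- bout
    }
    participants[[p$id]] <- p
    bouts[[p$id]] <- pb
    if (!is.null(out_dir)) write_participant_csvs(p, pb, out_dir)
  }
  list(participants = participants, bouts = bouts, conditions = conds)
}

# write the three CSV streams for one participant, bouts back-to-back
write_participant_csvs <- function(participant, bouts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  offset <- 0
  raw <- list(); lab <- list(); br <- list()
  for (bout in bouts) {
    tms <- rec_times(bout$recording) + offset
    raw[[length(raw) + 1]] <- data.frame(
      timestamp_s = tms,
      x_g = bout$recording$acc[, 1], y_g = bout$recording$acc[, 2],
      z_g = bout$recording$acc[, 3])
    lab[[length(lab) + 1]] <- data.frame(
      start_s = offset, end_s = offset + bout$duration_s,
      activity = bout$activity)
    br[[length(br) + 1]] <- data.frame(
      timestamp_s = bout$breaths$time_s + offset,
      vo2_lmin = bout$breaths$vo2_lmin, vco2_lmin = bout$breaths$vco2_lmin)
    offset <- offset + bout$duration_s
  }
  id <- participant$id
  utils::write.csv(do.call(rbind, raw),
                   file.path(out_dir, paste0(id, "_acc.csv")), row.names = FALSE)
  utils::write.csv(do.call(rbind, lab),
                   file.path(out_dir, paste0(id, "_labels.csv")), row.names = FALSE)
  utils::write.csv(do.call(rbind, br),
                   file.path(out_dir, paste0(id, "_breaths.csv")), row.names = FALSE)
  invisible(NULL)
}
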