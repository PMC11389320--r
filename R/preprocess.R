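#' Construct a raw triaxial recording
#'
#' The pipeline's universal input: uniformly (or near-uniformly) sampled
#' triaxial acceleration in g. Axis convention follows the thigh-worn
#' device: x = longitudinal (vertical axis of the thigh when standing
#' still), y = mediolateral, z = sagittal.
#'
#' @param acc N x 3 numeric matrix of acceleration in g.
#' @param sample_rate Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `"raw_recording"`.
#' @export
raw_recording <- function(acc, sample_rate, start_time = 0) {
  acc <- as.matrix(acc)
  stopifnot(ncol(acc) == 3, is.numeric(acc))
  if (!all(is.finite(acc))) stop("acceleration values must be finite")
  if (max(abs(acc)) > 8) {
    warning("acceleration exceeds the +/-8 g device range; clipping")
    acc[acc > 8] <- 8
    acc[acc < -8] <- -8
  }
  colnames(acc) <- c("x", "y", "z")
  structure(
    list(acc = acc, sample_rate = sample_rate, start_time = start_time),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d samples @ %.6g Hz (%.1f s), start %.3f s\n",
    nrow(x$acc), x$sample_rate, nrow(x$acc) / x$sample_rate, x$start_time
  ))
  invisible(x)
}

# sample timestamps (s) of a recording
rec_times <- function(rec) {
  rec$start_time + (seq_len(nrow(rec$acc)) - 1) / rec$sample_rate
}

#' Read a raw-acceleration CSV file
#'
#' Expects columns `timestamp_s, x_g, y_g, z_g` (header row, dot decimal).
#' The sample rate is estimated from the median timestamp delta;
#' non-monotone timestamps are rejected.
#'
#' @param path CSV file path.
#' @return A [raw_recording()].
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "x_g", "y_g", "z_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty recording file: ", path)
  for (cn in need) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop("non-numeric value in column ", cn, " at data line ",
           if (is.na(bad)) "?" else bad)
    }
  }
  dt <- diff(df$timestamp_s)
  if (any(dt <= 0)) {
    stop("non-monotone timestamp at data line ", which(dt <= 0)[1] + 1)
  }
  fs <- if (nrow(df) > 1) 1 / stats::median(dt) else NA_real_
  raw_recording(as.matrix(df[, c("x_g", "y_g", "z_g")]),
                sample_rate = fs, start_time = df$timestamp_s[1])
}

#' Write a raw-acceleration CSV file
#'
#' Inverse of [read_raw_csv()]; writes `timestamp_s, x_g, y_g, z_g`.
#'
#' @param rec A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(rec, path) {
  df <- data.frame(
    timestamp_s = rec_times(rec),
    x_g = rec$acc[, 1], y_g = rec$acc[, 2], z_g = rec$acc[, 3]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Linear interpolation onto a uniform grid at `target_hz`, spanning the
#' original time range. Used to guarantee the 100 Hz contract downstream.
#'
#' @param rec A [raw_recording()].
#' @param target_hz Target sampling rate (default 100).
#' @param times Optional vector of original sample times; defaults to the
#'   recording's nominal uniform times.
#' @return A [raw_recording()] at exactly `target_hz`.
#' @export
resample_uniform <- function(rec, target_hz = 100, times = NULL) {
  if (nrow(rec$acc) < 2) stop("cannot resample a recording with < 2 samples")
  if (is.null(times)) times <- rec_times(rec)
  stopifnot(length(times) == nrow(rec$acc))
  span <- times[length(times)] - times[1]
  # tolerate float rounding in parsed timestamps when sizing the grid
  n_out <- floor(span * target_hz + 1e-6) + 1
  new_t <- times[1] + (seq_len(n_out) - 1) / target_hz
  out <- vapply(1:3, function(j) {
    stats::approx(times, rec$acc[, j], xout = new_t, rule = 2)$y
  }, numeric(length(new_t)))
  raw_recording(out, sample_rate = target_hz, start_time = new_t[1])
}

# ---- zero-phase Butterworth filtering --------------------------------------

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) filtering with an odd-reflection pad to
#' suppress edge transients, so stride peak timing is not lag-shifted.
#' The effective magnitude response is the squared one-pass response: the
#' RMS gain at the cutoff frequency is 0.5, not 1/sqrt(2).
#'
#' @param x Numeric vector or N x k matrix (filtered column-wise).
#' @param order Filter order of one pass (8 for the main 20 Hz low-pass,
#'   4 for the 5 Hz stride filter).
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist.
#' @param fs_hz Sampling rate in Hz.
#' @return Filtered signal, same shape as `x`; DC gain 1.
#' @export
lowpass_butterworth <- function(x, order, cutoff_hz, fs_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    stop("cutoff must lie strictly between 0 and Nyquist (", fs_hz / 2, " Hz)")
  }
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n <= 3 * order) stop("signal too short for order-", order, " filtering")
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2))
  if (is.matrix(x)) {
    apply(x, 2, zero_phase_filter, bf = bf)
  } else {
    zero_phase_filter(x, bf)
  }
}

# odd-reflection padded forward-backward filtering (scipy filtfilt-style);
# the pad length is long enough for the start-up transient of the pass to
# decay below double precision for the orders/cutoffs used here.
zero_phase_filter <- function(x, bf, padlen = 500) {
  n <- length(x)
  p <- min(padlen, n - 1)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filter(bf, ext)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(p + 1):(p + n)])
}

# ---- autocalibration -------------------------------------------------------

#' Calibration parameters
#'
#' Per-axis gain/offset such that `corrected = gain * raw + offset`.
#'
#' @param gain Numeric length-3 gains (unitless).
#' @param offset Numeric length-3 offsets (g).
#' @param failed Logical; `TRUE` when calibration could not be estimated
#'   and identity parameters were returned.
#' @param n_static Number of static windows used.
#' @return An object of class `"calibration_params"`.
#' @export
calibration_params <- function(gain = c(1, 1, 1), offset = c(0, 0, 0),
                               failed = FALSE, n_static = NA_integer_) {
  structure(
    list(gain = as.numeric(gain), offset = as.numeric(offset),
         failed = isTRUE(failed), n_static = n_static),
    class = "calibration_params"
  )
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(
    "<calibration> gain (%.4f, %.4f, %.4f)  offset (%.4f, %.4f, %.4f) g%s\n",
    x$gain[1], x$gain[2], x$gain[3], x$offset[1], x$offset[2], x$offset[3],
    if (x$failed) "  [FAILED: identity]" else ""
  ))
  invisible(x)
}

# apply calibration to a recording
apply_calibration <- function(rec, params) {
  acc <- sweep(sweep(rec$acc, 2, params$gain, `*`), 2, params$offset, `+`)
  raw_recording(acc, rec$sample_rate, rec$start_time)
}

#' Autocalibrate a recording against local gravity
#'
#' Identifies low-movement windows (10-s windows whose per-axis SD is below
#' 0.013 g), then iteratively fits per-axis gain and offset so that the
#' static vector magnitudes converge to 1 g (weighted least squares against
#' the closest point on the unit sphere). If the static windows do not span
#' enough orientations (per-axis range of window means below the configured
#' threshold on at least two axes), identity parameters are returned with a
#' warning flag rather than an error.
#'
#' @param rec A [raw_recording()].
#' @param config Pipeline configuration (only `$preprocess` is used).
#' @param quiet Suppress the degenerate-input warning.
#' @return A list with elements `recording` (calibrated) and `params`
#'   (a [calibration_params()]).
#' @export
autocalibrate <- function(rec, config = default_config(), quiet = FALSE) {
  pc <- config$preprocess
  wlen <- round(pc$static_window_s * rec$sample_rate)
  n <- nrow(rec$acc)
  nwin <- n %/% wlen
  means <- NULL
  if (nwin >= 1) {
    idx <- rep(seq_len(nwin), each = wlen)
    keep <- logical(nwin)
    m <- matrix(0, nwin, 3)
    for (w in seq_len(nwin)) {
      rows <- ((w - 1) * wlen + 1):(w * wlen)
      sds <- apply(rec$acc[rows, , drop = FALSE], 2, stats::sd)
      if (all(sds < pc$static_sd_g)) {
        keep[w] <- TRUE
        m[w, ] <- colMeans(rec$acc[rows, , drop = FALSE])
      }
    }
    means <- m[keep, , drop = FALSE]
  }
  degenerate <- is.null(means) || nrow(means) < 3 ||
    sum(apply(means, 2, function(v) diff(range(v))) >
          pc$min_orientation_range_g) < 2
  if (degenerate) {
    if (!quiet) warning("insufficient static orientations; returning identity calibration")
    return(list(recording = rec,
                params = calibration_params(failed = TRUE,
                                            n_static = if (is.null(means)) 0L else nrow(means))))
  }
  gain <- c(1, 1, 1); offset <- c(0, 0, 0)
  pts <- means
  for (it in seq_len(pc$max_iter)) {
    cal <- sweep(sweep(pts, 2, gain, `*`), 2, offset, `+`)
    nrm <- sqrt(rowSums(cal^2))
    target <- cal / nrm
    new_gain <- gain; new_offset <- offset
    for (j in 1:3) {
      fit <- stats::lm.fit(cbind(1, cal[, j]), target[, j])
      new_offset[j] <- offset[j] * fit$coefficients[2] + fit$coefficients[1]
      new_gain[j] <- gain[j] * fit$coefficients[2]
    }
    delta <- max(abs(new_gain - gain), abs(new_offset - offset))
    gain <- new_gain; offset <- new_offset
    if (delta < pc$tol) break
  }
  ok <- all(abs(gain - 1) <= pc$max_gain_dev) && all(abs(offset) <= pc$max_offset_g)
  if (!ok) {
    if (!quiet) warning("calibration parameters outside sanity bounds; declared failed")
    return(list(recording = rec,
                params = calibration_params(failed = TRUE, n_static = nrow(means))))
  }
  params <- calibration_params(gain, offset, failed = FALSE, n_static = nrow(means))
  list(recording = apply_calibration(rec, params), params = params)
}

#' Estimate calibration from the six-sided cube routine
#'
#' Before each session the device is mounted in a cube and placed on each
#' side for ~10 s, exposing each axis to +1 g and -1 g. From the six static
#' segments the per-axis references give gain = 2 / (mean_pos - mean_neg)
#' and offset = -gain * (mean_pos + mean_neg) / 2.
#'
#' @param static_segments List of exactly six [raw_recording()]s, each at
#'   least 5 s long and dominated by one axis at +/-1 g.
#' @return A [calibration_params()].
#' @export
estimate_axis_references <- function(static_segments) {
  if (!is.list(static_segments) || length(static_segments) != 6) {
    stop("exactly six static segments are required (one per cube side)")
  }
  pos <- rep(NA_real_, 3); neg <- rep(NA_real_, 3)
  for (seg in static_segments) {
    if (nrow(seg$acc) < 5 * seg$sample_rate) {
      stop("each static segment must be at least 5 s long")
    }
    m <- colMeans(seg$acc)
    dom <- which.max(abs(m))
    if (abs(m[dom]) < 0.5) {
      stop("segment mis-oriented: dominant-axis magnitude ",
           sprintf("%.3f", abs(m[dom])), " g < 0.5 g")
    }
    if (m[dom] > 0) pos[dom] <- m[dom] else neg[dom] <- m[dom]
  }
  if (any(is.na(pos)) || any(is.na(neg))) {
    stop("segments must cover +1 g and -1 g on every axis")
  }
  gain <- 2 / (pos - neg)
  offset <- -gain * (pos + neg) / 2
  calibration_params(gain, offset)
}

# ---- epoching --------------------------------------------------------------

#' Construct an epoch set
#'
#' Compact container for a batch of 4-s epochs: a `n x L x 3` array of
#' windows plus a metadata data frame.
#'
#' @param windows Numeric array `n x L x 3`.
#' @param info Data frame with one row per epoch (`index`, `start_time`,
#'   `true_label`, `predicted_label`, ...).
#' @param probs Optional `n x 5` class-probability matrix.
#' @return An object of class `"epoch_set"`.
#' @export
epoch_set <- function(windows, info, probs = NULL) {
  stopifnot(length(dim(windows)) == 3, dim(windows)[3] == 3,
            nrow(info) == dim(windows)[1])
  structure(list(windows = windows, info = info, probs = probs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %d x 3 samples\n",
              dim(x$windows)[1], dim(x$windows)[2]))
  if (!all(is.na(x$info$true_label))) {
    print(table(x$info$true_label, useNA = "ifany"))
  }
  invisible(x)
}

#' @export
length.epoch_set <- function(x) dim(x$windows)[1]

#' Partition a recording into non-overlapping 4-s epochs
#'
#' Windows are half-open `[start, start + 4 s)`; the trailing partial
#' window is discarded. When an annotation is supplied, an epoch receives a
#' `true_label` only if a single label covers the whole window; epochs that
#' span a label boundary stay unlabelled (excluded from training, retained
#' for prediction).
#'
#' @param rec A [raw_recording()] at 100 Hz.
#' @param labels Optional annotation data frame with columns
#'   `start_s`, `end_s`, `activity` (half-open intervals).
#' @param config Pipeline configuration.
#' @return An [epoch_set()].
#' @export
make_epochs <- function(rec, labels = NULL, config = default_config()) {
  fs <- config$sample_rate_hz
  if (abs(rec$sample_rate - fs) > 1e-9) {
    stop("recording must be at ", fs, " Hz; run resample_uniform() first")
  }
  L <- config$epoch_s * fs
  n_ep <- nrow(rec$acc) %/% L
  if (n_ep == 0) {
    warning("recording shorter than one epoch; returning empty epoch set")
    return(epoch_set(array(0, c(0, L, 3)),
                     data.frame(index = integer(0), start_time = numeric(0),
                                true_label = character(0),
                                predicted_label = character(0))))
  }
  windows <- array(NA_real_, c(n_ep, L, 3))
  for (e in seq_len(n_ep)) {
    windows[e, , ] <- rec$acc[((e - 1) * L + 1):(e * L), ]
  }
  start_time <- rec$start_time + (seq_len(n_ep) - 1) * config$epoch_s
  true_label <- rep(NA_character_, n_ep)
  if (!is.null(labels)) {
    stopifnot(all(c("start_s", "end_s", "activity") %in% names(labels)))
    for (e in seq_len(n_ep)) {
      s <- start_time[e]; eend <- s + config$epoch_s
      cover <- labels$start_s <= s & labels$end_s >= eend
      if (sum(cover) == 1) true_label[e] <- labels$activity[cover]
    }
  }
  epoch_set(windows,
            data.frame(index = seq_len(n_ep) - 1L, start_time = start_time,
                       true_label = true_label,
                       predicted_label = NA_character_,
                       stringsAsFactors = FALSE))
}

#' Run the full preprocessing chain
#'
#' Fixed order: low-pass filter (8th-order Butterworth, 20 Hz), then
#' gravity autocalibration, then resampling to 100 Hz.
#'
#' @param rec A [raw_recording()].
#' @param config Pipeline configuration.
#' @param quiet Suppress autocalibration warnings (useful for short
#'   single-activity recordings with no static data).
#' @return A list with `recording` (preprocessed) and `calibration`.
#' @export
preprocess_recording <- function(rec, config = default_config(), quiet = FALSE) {
  pc <- config$preprocess
  filtered <- raw_recording(
    lowpass_butterworth(rec$acc, pc$lowpass_order, pc$lowpass_cutoff_hz,
                        rec$sample_rate),
    rec$sample_rate, rec$start_time
  )
  cal <- autocalibrate(filtered, config, quiet = quiet)
  out <- resample_uniform(cal$recording, config$sample_rate_hz)
  list(recording = out, calibration = cal$params)
}

#' Serialise calibration parameters to JSON
#'
#' @param params A [calibration_params()].
#' @param path Output path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(params, path) {
  jsonlite::write_json(
    list(gain = params$gain, offset = params$offset,
         failed = params$failed, n_static = params$n_static),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
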