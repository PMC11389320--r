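# Stride segmentation: activity-specific axis selection and filtering,
# peak detection, and Fourier time-normalisation to 30 bins.

#' Select and filter the stride-detection signal
#'
#' For walking the sagittal axis (z) is used; for running and cycling the
#' thigh-longitudinal axis (x). The selected axis is passed through a
#' 4th-order zero-phase Butterworth low-pass at 5 Hz.
#'
#' @param acc M x 3 acceleration matrix of one activity sequence (g).
#' @param activity One of walking/running/cycling.
#' @param fs Sampling rate in Hz (default 100).
#' @param config Pipeline configuration.
#' @return Numeric vector: the filtered stride-axis signal.
#' @export
select_stride_signal <- function(acc, activity, fs = 100,
                                 config = default_config()) {
  sc <- config$strides
  if (!activity %in% names(sc$stride_axis)) {
    stop("no strides are defined for activity: ", activity)
  }
  axis <- sc$stride_axis[[activity]]
  lowpass_butterworth(acc[, axis], sc$filter_order, sc$filter_cutoff_hz, fs)
}

#' Detect stride peaks
#'
#' Local maxima of the filtered stride signal subject to (a) a minimum
#' inter-peak distance of `0.8 / f_max(activity)` seconds, where `f_max`
#' is the activity's maximum plausible stride frequency, and (b) a
#' topographic prominence of at least 0.3 times the signal's standard
#' deviation. Candidates are accepted greedily in order of decreasing
#' height.
#'
#' @param x Filtered signal from [select_stride_signal()].
#' @param activity One of walking/running/cycling.
#' @param fs Sampling rate in Hz.
#' @param config Pipeline configuration.
#' @return Strictly increasing integer vector of peak sample indices
#'   (1-based). Empty, with a warning, when the signal is shorter than one
#'   minimum stride.
#' @export
detect_stride_peaks <- function(x, activity, fs = 100,
                                config = default_config()) {
  sc <- config$strides
  if (!activity %in% names(sc$max_freq_hz)) {
    stop("no strides are defined for activity: ", activity)
  }
  min_dist <- round(0.8 / sc$max_freq_hz[[activity]] * fs)
  if (length(x) <= min_dist) {
    warning("signal shorter than one minimum stride; no peaks")
    return(integer(0))
  }
  cand <- local_maxima(x)
  if (!length(cand)) return(integer(0))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= sc$prominence_factor * stats::sd(x)]
  if (!length(cand)) return(integer(0))
  enforce_min_distance(cand, x[cand], min_dist)
}

# strict local maxima; plateaus take their first sample
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# topographic prominence of each peak: height above the higher of the two
# lowest saddles separating it from higher terrain (signal ends count as
# boundaries, as in standard peak-prominence definitions)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until a higher sample or the boundary
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    left_base <- lmin
    rmin <- h
    i <- p + 1L
    n <- length(x)
    while (i <= n && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    right_base <- rmin
    h - max(left_base, right_base)
  }, numeric(1))
}

# greedy minimum-distance enforcement, tallest peaks first
enforce_min_distance <- function(idx, height, min_dist) {
  ord <- order(height, decreasing = TRUE)
  accepted <- integer(0)
  for (i in ord) {
    p <- idx[i]
    if (!length(accepted) || all(abs(accepted - p) >= min_dist)) {
      accepted <- c(accepted, p)
    }
  }
  sort(accepted)
}

#' Fourier time-normalisation of a stride
#'
#' Band-limited resampling of each axis from M samples to `n_bins`:
#' forward FFT, symmetric spectrum truncation (or zero-padding), inverse
#' FFT with amplitude rescaling. The mean (DC component) of each axis is
#' preserved exactly.
#'
#' @param raw_segment M x 3 acceleration matrix of one stride (M >= 4).
#' @param n_bins Output length (default 30).
#' @return `n_bins` x 3 matrix.
#' @export
normalize_stride <- function(raw_segment, n_bins = 30) {
  raw_segment <- as.matrix(raw_segment)
  if (nrow(raw_segment) < 4) stop("stride segment must have at least 4 samples")
  apply(raw_segment, 2, resample_fft, n_out = n_bins)
}

# band-limited resampling of a real vector (scipy.signal.resample logic)
resample_fft <- function(x, n_out) {
  m <- length(x)
  if (m == n_out) return(x)
  X <- stats::fft(x)
  Y <- complex(real = rep(0, n_out), imaginary = rep(0, n_out))
  nk <- min(m, n_out)
  half <- nk %/% 2
  # positive frequencies (incl. DC)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  # negative frequencies
  if (half > 1) {
    Y[(n_out - half + 2):n_out] <- X[(m - half + 2):m]
  }
  if (nk %% 2 == 0) {
    # split/merge the Nyquist bin
    if (n_out < m) {
      # folded energy from the two half-Nyquist bins
      Y[half + 1] <- X[half + 1] + X[m - half + 1]
    } else {
      Y[half + 1] <- X[half + 1] / 2
      Y[n_out - half + 1] <- Conj(X[half + 1]) / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / m
}

#' Stride container
#'
#' Bundles per-stride metadata with the 30 x 3 time-normalised shapes.
#'
#' @param info Data frame with columns `activity`, `start_sample`,
#'   `end_sample`, `duration_s` (one row per stride).
#' @param shapes Array `n x 30 x 3` of normalised stride shapes.
#' @param n_rejected Count of candidate strides discarded by the
#'   plausibility windows.
#' @return An object of class `"stride_set"`.
#' @export
stride_set <- function(info, shapes, n_rejected = 0L) {
  stopifnot(nrow(info) == dim(shapes)[1])
  structure(list(info = info, shapes = shapes, n_rejected = n_rejected),
            class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf("<stride_set> %d strides (%d rejected as implausible)\n",
              nrow(x$info), x$n_rejected))
  if (nrow(x$info)) print(table(x$info$activity))
  invisible(x)
}

#' @export
length.stride_set <- function(x) nrow(x$info)

# empty stride set constructor
empty_stride_set <- function(n_bins = 30) {
  stride_set(data.frame(activity = character(0), start_sample = integer(0),
                        end_sample = integer(0), duration_s = numeric(0)),
             array(0, c(0, n_bins, 3)))
}

#' Extract strides between consecutive peaks
#'
#' One stride per consecutive peak pair (peak-to-peak, half-open
#' `[peak_i, peak_{i+1})`). Strides whose duration falls outside the
#' activity's plausibility window (walking 0.8-1.7 s, running
#' 0.55-0.85 s, cycling 0.7-1.1 s) are discarded and counted. Surviving
#' strides are time-normalised to 30 x 3 via [normalize_stride()].
#'
#' @param acc M x 3 acceleration matrix of the sequence (g).
#' @param peaks Peak indices from [detect_stride_peaks()].
#' @param activity One of walking/running/cycling.
#' @param fs Sampling rate in Hz.
#' @param config Pipeline configuration.
#' @return A [stride_set()]. Empty (with a warning) for < 2 peaks.
#' @export
extract_strides <- function(acc, peaks, activity, fs = 100,
                            config = default_config()) {
  sc <- config$strides
  n_bins <- sc$n_bins
  if (length(peaks) < 2) {
    warning("fewer than 2 peaks; no strides extracted")
    return(empty_stride_set(n_bins))
  }
  bounds <- sc$duration_bounds[[activity]]
  if (is.null(bounds)) stop("no strides are defined for activity: ", activity)
  starts <- peaks[-length(peaks)]
  ends <- peaks[-1]
  dur <- (ends - starts) / fs
  ok <- dur >= bounds[1] & dur <= bounds[2]
  n_rej <- sum(!ok)
  starts <- starts[ok]; ends <- ends[ok]; dur <- dur[ok]
  if (!length(starts)) return(stride_set(empty_stride_set(n_bins)$info,
                                         array(0, c(0, n_bins, 3)), n_rej))
  shapes <- array(NA_real_, c(length(starts), n_bins, 3))
  for (i in seq_along(starts)) {
    seg <- acc[starts[i]:(ends[i] - 1L), , drop = FALSE]
    shapes[i, , ] <- normalize_stride(seg, n_bins)
  }
  stride_set(
    data.frame(activity = activity, start_sample = starts,
               end_sample = ends, duration_s = dur),
    shapes, n_rej
  )
}

#' Segment all strides of a classified recording
#'
#' Runs axis selection, peak detection and stride extraction within each
#' walking/running/cycling sequence and concatenates the results. Sample
#' indices are relative to the full recording.
#'
#' @param acc N x 3 acceleration matrix of the whole recording.
#' @param sequences Data frame from [group_sequences()].
#' @param fs Sampling rate in Hz.
#' @param config Pipeline configuration.
#' @return A [stride_set()] with an extra `sequence_id` column.
#' @export
segment_sequences <- function(acc, sequences, fs = 100,
                              config = default_config()) {
  keep <- sequences$activity %in% c("walking", "running", "cycling")
  parts <- list()
  n_rej <- 0L
  for (s in which(keep)) {
    rows <- sequences$start_sample[s]:(sequences$end_sample[s])
    sub <- acc[rows[rows <= nrow(acc)], , drop = FALSE]
    act <- sequences$activity[s]
    sig <- try(select_stride_signal(sub, act, fs, config), silent = TRUE)
    if (inherits(sig, "try-error")) next
    pk <- suppressWarnings(detect_stride_peaks(sig, act, fs, config))
    st <- suppressWarnings(extract_strides(sub, pk, act, fs, config))
    n_rej <- n_rej + st$n_rejected
    if (nrow(st$info)) {
      st$info$start_sample <- st$info$start_sample + sequences$start_sample[s] - 1L
      st$info$end_sample <- st$info$end_sample + sequences$start_sample[s] - 1L
      st$info$sequence_id <- s
      parts[[length(parts) + 1]] <- st
    }
  }
  if (!length(parts)) {
    out <- empty_stride_set(config$strides$n_bins)
    out$info$sequence_id <- integer(0)
    out$n_rejected <- n_rej
    return(out)
  }
  info <- do.call(rbind, lapply(parts, `[[`, "info"))
  shapes <- do.call(abind3, lapply(parts, `[[`, "shapes"))
  stride_set(info, shapes, n_rej)
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  arrs <- arrs[vapply(arrs, function(a) dim(a)[1] > 0, logical(1))]
  if (!length(arrs)) return(array(0, c(0, 30, 3)))
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(total, d[2], d[3]))
  at <- 1L
  for (a in arrs) {
    k <- dim(a)[1]
    out[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  out
}

#' Write a stride table CSV
#'
#' One row per stride: sequence id, stride id, activity, start time,
#' duration, then 90 shape columns `x_bin00 ... z_bin29`.
#'
#' @param strides A [stride_set()].
#' @param path Output path.
#' @param fs Sampling rate used to convert sample indices to seconds.
#' @return `path`, invisibly.
#' @export
write_stride_csv <- function(strides, path, fs = 100) {
  n <- nrow(strides$info)
  n_bins <- dim(strides$shapes)[2]
  shp <- matrix(aperm(strides$shapes, c(1, 2, 3)), nrow = n)
  flat <- do.call(cbind, lapply(1:3, function(ax) strides$shapes[, , ax, drop = FALSE][, , 1, drop = TRUE]))
  if (n == 1) flat <- matrix(unlist(lapply(1:3, function(ax) strides$shapes[1, , ax])), nrow = 1)
  colnames(flat) <- as.vector(vapply(c("x", "y", "z"), function(a) {
    sprintf("%s_bin%02d", a, 0:(n_bins - 1))
  }, character(n_bins)))
  df <- data.frame(
    sequence_id = if ("sequence_id" %in% names(strides$info)) strides$info$sequence_id else NA,
    stride_id = seq_len(n),
    activity = strides$info$activity,
    start_s = (strides$info$start_sample - 1) / fs,
    duration_s = strides$info$duration_s
  )
  utils::write.csv(cbind(df, flat), path, row.names = FALSE)
  invisible(path)
}
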