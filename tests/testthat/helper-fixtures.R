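# Shared fixtures, built in code at test time.

# a perfectly static recording at a given gravity orientation
static_recording <- function(orientation, duration_s = 12, fs = 100,
                             noise_sd = 0) {
  n <- duration_s * fs
  acc <- matrix(rep(orientation, each = n), n, 3)
  if (noise_sd > 0) acc <- acc + matrix(rnorm(n * 3, 0, noise_sd), n, 3)
  raw_recording(acc, fs)
}

# recording holding a pure sinusoid on one axis (others zero)
sinusoid_recording <- function(freq_hz, duration_s, fs = 100, axis = 1,
                               amplitude = 1) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  acc <- matrix(0, n, 3)
  acc[, axis] <- amplitude * sin(2 * pi * freq_hz * t)
  raw_recording(acc, fs)
}

# RMS amplitude of the central portion of a signal (avoids edge effects)
mid_rms <- function(x, frac = 0.6) {
  n <- length(x)
  lo <- floor(n * (1 - frac) / 2) + 1
  sqrt(mean(x[lo:(lo + floor(n * frac))]^2))
}

# default test participant with zero sensor noise (deterministic signals)
noiseless_participant <- function(seed = 101) {
  p <- synthetic_participant("T01", seed)
  p$noise_sd <- 0
  p
}

# ---- memoised full-scale experiment shared by the acceptance tests --------
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_experiment <- function() {
  if (is.null(.acceptance_cache$experiment)) {
    cfg <- default_config()   # 16 participants, 12 train / 4 test, seed 1
    .acceptance_cache$experiment <- run_experiment(cfg, quiet = TRUE)
  }
  .acceptance_cache$experiment
}
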