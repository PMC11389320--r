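# Energy-expenditure models: aggregated-metric linear baselines
# (ENMO / MAD, with or without activity type and its interaction), the
# stride-level temporal convolutional network, and the CATSE3 composite
# that routes sitting/standing epochs to the ENMO + activity regression
# and walking/running/cycling epochs to the stride model.

# ---- aggregated acceleration metrics ---------------------------------------

#' Euclidean Norm Minus One of an epoch
#'
#' Mean over samples of `max(||a|| - 1, 0)` with `||a||` the per-sample
#' Euclidean norm in g (negative deviations are truncated before
#' averaging).
#'
#' @param window L x 3 acceleration matrix (g).
#' @return ENMO in g (non-negative).
#' @export
compute_enmo <- function(window) {
  if (any(!is.finite(window))) stop("non-finite samples in window")
  nrm <- sqrt(rowSums(window^2))
  mean(pmax(nrm - 1, 0))
}

#' Mean Amplitude Deviation of an epoch
#'
#' Mean over samples of `| ||a|| - mean(||a||) |` within the epoch.
#'
#' @param window L x 3 acceleration matrix (g).
#' @return MAD in g (non-negative).
#' @export
compute_mad <- function(window) {
  if (any(!is.finite(window))) stop("non-finite samples in window")
  nrm <- sqrt(rowSums(window^2))
  mean(abs(nrm - mean(nrm)))
}

#' Fill ENMO and MAD for every epoch
#'
#' @param epochs An [epoch_set()].
#' @return The epoch set with `info$enmo` and `info$mad` filled.
#' @export
compute_epoch_metrics <- function(epochs) {
  n <- dim(epochs$windows)[1]
  enmo <- numeric(n); mad <- numeric(n)
  for (i in seq_len(n)) {
    w <- epochs$windows[i, , ]
    nrm <- sqrt(rowSums(w^2))
    enmo[i] <- mean(pmax(nrm - 1, 0))
    mad[i] <- mean(abs(nrm - mean(nrm)))
  }
  epochs$info$enmo <- enmo
  epochs$info$mad <- mad
  epochs
}

# ---- linear baseline models ------------------------------------------------

#' Fit a linear energy-expenditure model
#'
#' Ordinary least squares of steady-state EE (kcal/kg/min) on an
#' aggregated acceleration metric, optionally with activity type and its
#' interaction with the metric (reference activity: sitting).
#'
#' @param data Data frame with columns `ee`, the metric column named by
#'   `metric` (`"enmo"` or `"mad"`), and `activity` when
#'   `with_activity = TRUE`.
#' @param metric `"enmo"` or `"mad"`.
#' @param with_activity Include activity dummies and interactions.
#' @return An object of class `"linear_ee_model"` with the fitted `lm`,
#'   the coefficient table, `r2` and residual SD.
#' @export
fit_linear_ee <- function(data, metric = c("enmo", "mad"),
                          with_activity = FALSE) {
  metric <- match.arg(metric)
  stopifnot(all(c("ee", metric) %in% names(data)))
  if (nrow(data) < 10) stop("need at least 10 observations")
  df <- data.frame(ee = data$ee, m = data[[metric]])
  if (with_activity) {
    if (!"activity" %in% names(data)) stop("with_activity requires an activity column")
    acts <- intersect(activity_levels(), unique(data$activity))
    if (length(acts) < 2) stop("with_activity requires >= 2 activities present")
    df$activity <- factor(data$activity, levels = acts)
    fit <- stats::lm(ee ~ m * activity, data = df)
  } else {
    fit <- stats::lm(ee ~ m, data = df)
  }
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  s <- summary(fit)
  structure(list(
    metric = metric,
    with_activity = with_activity,
    fit = fit,
    coefficients = cf,
    activities = if (with_activity) levels(df$activity) else NULL,
    r2 = s$r.squared,
    residual_sd = s$sigma,
    n = nrow(df)
  ), class = "linear_ee_model")
}

#' @export
print.linear_ee_model <- function(x, ...) {
  cat(sprintf("<linear_ee_model> EE ~ %s%s, n = %d, R2 = %.4f\n",
              toupper(x$metric),
              if (x$with_activity) " * activity" else "", x$n, x$r2))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Predict energy expenditure from a linear model
#'
#' Affine prediction in the metric for the given activity, truncated
#' below at zero (truncations are counted in the returned attribute).
#'
#' @param model A [fit_linear_ee()] model.
#' @param metric_value Numeric vector of metric values (g).
#' @param activity Activity labels (required and checked when the model
#'   includes activity).
#' @return Numeric vector of EE (kcal/kg/min, >= 0) with attribute
#'   `n_truncated`.
#' @export
predict_linear_ee <- function(model, metric_value, activity = NULL) {
  nd <- data.frame(m = metric_value)
  if (model$with_activity) {
    if (is.null(activity)) stop("model includes activity; supply activity labels")
    unseen <- setdiff(unique(activity), model$activities)
    if (length(unseen)) {
      stop("activity level(s) not seen during fitting: ",
           paste(unseen, collapse = ", "))
    }
    nd$activity <- factor(activity, levels = model$activities)
  }
  p <- unname(stats::predict(model$fit, newdata = nd))
  n_trunc <- sum(p < 0)
  p <- pmax(p, 0)
  attr(p, "n_truncated") <- n_trunc
  p
}

# ---- temporal convolutional network ----------------------------------------

#' Build an untrained stride energy-expenditure model
#'
#' Temporal convolutional network over the 30 x 3 time-normalised stride.
#' A fixed front end augments the three raw channels with their
#' per-stride RMS-normalised copies (separating amplitude-invariant
#' waveform shape from overall amplitude) and broadcasts the 3-way
#' activity one-hot as constant channels, so convolution features are
#' activity-conditioned from the first layer (30 x 9 in total). The
#' temporal stack is residual blocks of dilated causal convolutions
#' (dilations 1/2/4/8, kernel 3, ReLU), mean-pooled over time,
#' concatenated with the log RMS amplitude and the activity encoding at
#' a ReLU dense head with a scalar linear output. Deterministic given
#' `seed`.
#'
#' @param config Pipeline configuration (`$tcn` section).
#' @param seed Integer seed for initialisation.
#' @return An object of class `"tcn_ee_model"`.
#' @export
build_tcn_ee <- function(config = default_config(), seed = 1L) {
  tc <- config$tcn
  k <- tc$kernel; F <- tc$filters
  with_seed(seed, {
    params <- list()
    C_in <- 9L          # raw + RMS-normalised + activity one-hot channels
    for (l in seq_along(tc$dilations)) {
      params[[paste0("Wc", l)]] <- glorot_uniform(k * C_in, F)
      params[[paste0("bc", l)]] <- numeric(F)
      C_in <- F
    }
    params$Ws <- glorot_uniform(9, F)   # skip projection for the first block
    params$Wd1 <- glorot_uniform(F + 1 + 3, tc$dense_units)
    params$bd1 <- numeric(tc$dense_units)
    params$Wd2 <- glorot_uniform(tc$dense_units, 1)
    params$bd2 <- numeric(1)
    # wide path: per-activity affine term in log amplitude, added to the
    # output so the amplitude baseline is representable exactly and the
    # temporal stack only has to learn the residual shape effects
    params$Wl <- matrix(0, 6, 1)
    structure(list(
      params = params, config = tc,
      gait_levels = c("walking", "running", "cycling"),
      n_bins = config$strides$n_bins,
      seed = seed, trained = FALSE, history = NULL,
      y_mean = 0, y_sd = 1,
      config_hash = config_hash(tc)
    ), class = "tcn_ee_model")
  })
}

#' @export
print.tcn_ee_model <- function(x, ...) {
  cat(sprintf(
    "<tcn_ee_model> dilations %s, %d filters, kernel %d; %s\n",
    paste(x$config$dilations, collapse = "/"), x$config$filters,
    x$config$kernel, if (x$trained) "trained" else "untrained"
  ))
  invisible(x)
}

# circularly shift each stride along time by its own offset (augmentation:
# one gait cycle is periodic, so a rotation is another valid alignment)
circular_shift_strides <- function(X, shifts) {
  T <- dim(X)[2]
  for (i in seq_along(shifts)) {
    k <- shifts[i]
    if (k > 0) X[i, , ] <- X[i, c((k + 1):T, 1:k), ]
  }
  X
}

# fixed input front end (no trainable parameters, no gradient needed):
# raw channels, their per-stride RMS-normalised copies, and the activity
# one-hot broadcast as constant channels, so convolution features are
# activity-conditioned from the first layer
tcn_inputs <- function(X, A) {
  d <- dim(X); B <- d[1]; T <- d[2]
  amp <- sqrt(apply(X^2, 1, mean)) + 1e-8
  X9 <- array(0, c(B, T, 9))
  X9[, , 1:3] <- X
  X9[, , 4:6] <- X / amp               # amp recycles over the first dim
  for (j in 1:3) X9[, , 6 + j] <- matrix(A[, j], B, T)
  list(X9 = X9, log_amp = matrix(log(amp), B, 1))
}

tcn_forward <- function(params, X, A, cfg) {
  inp <- tcn_inputs(X, A)
  Z <- inp$X9
  d <- dim(Z); B <- d[1]; T <- d[2]
  F <- cfg$filters
  caches <- vector("list", length(cfg$dilations))
  for (l in seq_along(cfg$dilations)) {
    cv <- conv1d_forward(Z, params[[paste0("Wc", l)]], params[[paste0("bc", l)]],
                         dilation = cfg$dilations[l], pad = "causal")
    rl <- relu_forward(cv$out)
    if (l == 1) {
      skip <- array(matrix(Z, B * T, 9) %*% params$Ws, c(B, T, F))
      Znew <- rl$out + skip
      caches[[l]] <- list(cv = cv, rl = rl, Zin = Z)
    } else {
      Znew <- rl$out + Z
      caches[[l]] <- list(cv = cv, rl = rl)
    }
    Z <- Znew
  }
  P <- colMeans(aperm(Z, c(2, 1, 3)))          # mean over time -> [B, F]
  if (B == 1) P <- matrix(P, 1, F)
  h <- cbind(P, inp$log_amp, A)
  d1 <- dense_forward(h, params$Wd1, params$bd1)
  r1 <- relu_forward(d1$out)
  d2 <- dense_forward(r1$out, params$Wd2, params$bd2)
  h_lin <- cbind(A, A * as.numeric(inp$log_amp))
  out <- as.numeric(d2$out) + as.numeric(h_lin %*% params$Wl)
  list(out = out,
       cache = list(blocks = caches, T = T, B = B, F = F,
                    d1 = d1, r1 = r1, d2 = d2, h_lin = h_lin))
}

tcn_backward <- function(params, dout, cache, cfg) {
  B <- cache$B; T <- cache$T; F <- cache$F
  grads <- list()
  grads$Wl <- crossprod(cache$h_lin, matrix(dout, B, 1))
  dd2 <- dense_backward(matrix(dout, B, 1), params$Wd2, cache$d2$cache)
  grads$Wd2 <- dd2$dW; grads$bd2 <- dd2$db
  dr1 <- relu_backward(dd2$dX, cache$r1$cache)
  dd1 <- dense_backward(dr1, params$Wd1, cache$d1$cache)
  grads$Wd1 <- dd1$dW; grads$bd1 <- dd1$db
  dP <- dd1$dX[, 1:F, drop = FALSE]
  dZ <- aperm(array(dP / T, c(B, F, T)), c(1, 3, 2))
  for (l in rev(seq_along(cfg$dilations))) {
    cb <- cache$blocks[[l]]
    dRelu <- relu_backward(dZ, cb$rl$cache)
    bc <- conv1d_backward(dRelu, params[[paste0("Wc", l)]], cb$cv$cache)
    grads[[paste0("Wc", l)]] <- bc$dW
    grads[[paste0("bc", l)]] <- bc$db
    if (l == 1) {
      dZmat <- matrix(dZ, B * T, F)
      grads$Ws <- crossprod(matrix(cb$Zin, B * T, 9), dZmat)
      # gradients wrt the (fixed) input features are not needed further
    } else {
      dZ <- bc$dX + dZ
    }
  }
  grads
}

gait_one_hot <- function(activity, levels) {
  bad <- setdiff(unique(activity), levels)
  if (length(bad)) {
    stop("strides must be walking/running/cycling; got: ",
         paste(bad, collapse = ", "))
  }
  one_hot(activity, levels)
}

tcn_val_loss <- function(params, X, A, y, cfg, batch = 512L) {
  n <- dim(X)[1]
  tot <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    fw <- tcn_forward(params, X[s:e, , , drop = FALSE], A[s:e, , drop = FALSE], cfg)
    tot <- tot + sum((fw$out - y[s:e])^2)
  }
  tot / n
}

#' Train the stride energy-expenditure model
#'
#' Minimises mean squared error (on internally standardised targets) with
#' Adam; per-participant train/validation split; the best-validation
#' weights are retained. During training each stride's reference EE is
#' the steady-state EE of its bout. Deterministic given `seed`.
#'
#' @param model A [build_tcn_ee()] model.
#' @param strides A [stride_set()] whose `info` has `activity`, `ref_ee`
#'   and (for the subject-wise split) `participant`.
#' @param config Pipeline configuration.
#' @param seed Integer seed.
#' @return The trained model with a `history` data frame.
#' @export
train_tcn_ee <- function(model, strides, config = default_config(), seed = 1L) {
  tc <- config$tcn
  info <- strides$info
  stopifnot(all(c("activity", "ref_ee") %in% names(info)))
  if (dim(strides$shapes)[2] != model$n_bins || dim(strides$shapes)[3] != 3) {
    stop("strides must be ", model$n_bins, " x 3")
  }
  X <- strides$shapes
  A <- gait_one_hot(info$activity, model$gait_levels)
  if (any(info$ref_ee <= 0)) stop("reference EE must be positive")
  model$log_target <- isTRUE(tc$log_target)
  y_raw <- if (model$log_target) log(info$ref_ee) else info$ref_ee
  model$y_mean <- mean(y_raw)
  model$y_sd <- stats::sd(y_raw)
  if (!is.finite(model$y_sd) || model$y_sd == 0) model$y_sd <- 1
  y <- (y_raw - model$y_mean) / model$y_sd
  part <- if ("participant" %in% names(info)) info$participant else NULL

  with_seed(seed, {
    n <- dim(X)[1]
    if (!is.null(part) && length(unique(part)) >= 2) {
      ids <- unique(part)
      val_ids <- sample(ids, max(1L, round(tc$val_fraction * length(ids))))
      val <- part %in% val_ids
    } else {
      warning("no usable participant column; random stride split")
      val <- seq_len(n) %in% sample.int(n, max(1L, round(tc$val_fraction * n)))
    }
    Xtr <- X[!val, , , drop = FALSE]; Atr <- A[!val, , drop = FALSE]; ytr <- y[!val]
    Xva <- X[val, , , drop = FALSE]; Ava <- A[val, , drop = FALSE]; yva <- y[val]
    params <- model$params
    state <- adam_init(params)
    best <- list(loss = Inf, params = params)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    wait <- 0L
    wd <- if (is.null(tc$weight_decay)) 0 else tc$weight_decay
    for (ep in seq_len(tc$n_epochs)) {
      tr_loss <- 0
      for (b in minibatches(dim(Xtr)[1], tc$batch_size)) {
        Xb <- Xtr[b, , , drop = FALSE]
        if (isTRUE(tc$augment_shift)) {
          Xb <- circular_shift_strides(Xb, sample.int(dim(Xb)[2], length(b),
                                                      replace = TRUE) - 1L)
        }
        fw <- tcn_forward(params, Xb, Atr[b, , drop = FALSE], tc)
        ls <- mse_loss(fw$out, ytr[b])
        grads <- tcn_backward(params, ls$dpred, fw$cache, tc)
        if (wd > 0) {
          for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + wd * params[[nm]]
        }
        upd <- adam_step(params, grads, state, lr = tc$learning_rate)
        params <- upd$params; state <- upd$state
        tr_loss <- tr_loss + ls$loss * length(b)
      }
      tr_loss <- tr_loss / dim(Xtr)[1]
      va_loss <- tcn_val_loss(params, Xva, Ava, yva, tc)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                     val_loss = va_loss))
      if (va_loss < best$loss) {
        best <- list(loss = va_loss, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) break
      }
    }
    model$params <- best$params
    model$trained <- TRUE
    model$history <- hist
    model$val_loss <- best$loss
    model
  })
}

#' Predict per-stride energy expenditure
#'
#' @param model A trained [build_tcn_ee()] model.
#' @param strides A [stride_set()] of walking/running/cycling strides.
#' @return Numeric vector of EE (kcal/kg/min), floored at 0 with
#'   attribute `n_truncated`.
#' @export
predict_stride_ee <- function(model, strides, batch = 512L) {
  if (!model$trained) stop("stride EE model has not been trained")
  n <- nrow(strides$info)
  if (n == 0) return(numeric(0))
  A <- gait_one_hot(strides$info$activity, model$gait_levels)
  X <- strides$shapes
  # average over circular time-shifts: training enforces approximate phase
  # invariance, so averaging the remaining phase sensitivity out reduces
  # prediction variance at no modelling cost
  n_tta <- model$config$tta_shifts
  if (is.null(n_tta) || !isTRUE(model$config$augment_shift)) n_tta <- 1L
  T <- dim(X)[2]
  shifts <- round(seq(0, T, length.out = n_tta + 1L))[seq_len(n_tta)]
  out <- numeric(n)
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    acc <- numeric(e - s + 1)
    for (k in shifts) {
      Xb <- X[s:e, , , drop = FALSE]
      if (k > 0) Xb <- circular_shift_strides(Xb, rep(k, e - s + 1))
      acc <- acc + tcn_forward(model$params, Xb,
                               A[s:e, , drop = FALSE], model$config)$out
    }
    out[s:e] <- acc / length(shifts)
  }
  p <- out * model$y_sd + model$y_mean
  if (isTRUE(model$log_target)) p <- exp(p)
  n_trunc <- sum(p < 0)
  p <- pmax(p, 0)
  attr(p, "n_truncated") <- n_trunc
  p
}

# ---- composite assembly ----------------------------------------------------

#' Assemble the composite energy-expenditure time series
#'
#' Routing per classified epoch: sitting/standing epochs get the
#' ENMO + activity regression prediction (`source = "regression"`);
#' walking/running/cycling epochs get the mean predicted EE of the
#' strides overlapping the epoch (half-open overlap,
#' `source = "stride_model"`); a gait epoch with no overlapping strides
#' falls back to the regression (`source = "fallback"`). Every input
#' epoch appears exactly once, in time order.
#'
#' @param epochs A classified [epoch_set()] with ENMO filled (see
#'   [compute_epoch_metrics()]).
#' @param strides A [stride_set()] from [segment_sequences()] (sample
#'   indices relative to the same recording).
#' @param tcn_model A trained [build_tcn_ee()] model.
#' @param linear_model A fitted ENMO + activity [fit_linear_ee()] model.
#' @param config Pipeline configuration.
#' @return A data frame of class `"ee_timeseries"` with columns
#'   `epoch_index`, `start_s`, `activity`, `ee_kcal_kg_min`, `source`.
#' @export
compose_catse3 <- function(epochs, strides, tcn_model, linear_model,
                           config = default_config()) {
  if (is.null(tcn_model) || !inherits(tcn_model, "tcn_ee_model")) {
    stop("missing component: trained stride EE model")
  }
  if (is.null(linear_model) || !inherits(linear_model, "linear_ee_model")) {
    stop("missing component: fitted ENMO + activity regression")
  }
  if (!linear_model$with_activity) {
    stop("the regression component must include activity type")
  }
  info <- epochs$info
  if (any(is.na(info$predicted_label))) stop("epochs must be classified first")
  if (is.null(info$enmo)) stop("epoch ENMO missing; run compute_epoch_metrics()")
  L <- config$epoch_s * config$sample_rate_hz
  n <- nrow(info)
  stride_pred <- if (nrow(strides$info)) predict_stride_ee(tcn_model, strides) else numeric(0)
  ee <- numeric(n)
  src <- character(n)
  reg_all <- predict_linear_ee(linear_model, info$enmo, info$predicted_label)
  gait <- info$predicted_label %in% c("walking", "running", "cycling")
  for (i in seq_len(n)) {
    if (!gait[i]) {
      ee[i] <- reg_all[i]
      src[i] <- "regression"
      next
    }
    ep_start <- (i - 1L) * L + 1L
    ep_end <- i * L                      # inclusive last sample
    ov <- which(strides$info$start_sample <= ep_end &
                  strides$info$end_sample > ep_start)
    if (length(ov)) {
      ee[i] <- mean(stride_pred[ov])
      src[i] <- "stride_model"
    } else {
      ee[i] <- reg_all[i]
      src[i] <- "fallback"
    }
  }
  out <- data.frame(epoch_index = info$index, start_s = info$start_time,
                    activity = info$predicted_label,
                    ee_kcal_kg_min = ee, source = src,
                    stringsAsFactors = FALSE)
  class(out) <- c("ee_timeseries", "data.frame")
  out
}

#' @export
print.ee_timeseries <- function(x, ...) {
  cat(sprintf("<ee_timeseries> %d epochs; mean EE %.4f kcal/kg/min\n",
              nrow(x), mean(x$ee_kcal_kg_min)))
  print(table(source = x$source))
  invisible(x)
}

#' Write an energy-expenditure time series to CSV
#'
#' @param ee_ts An `ee_timeseries` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ee_csv <- function(ee_ts, path) {
  utils::write.csv(as.data.frame(ee_ts), path, row.names = FALSE)
  invisible(path)
}

#' Serialise a linear model's coefficients to JSON
#'
#' @param model A [fit_linear_ee()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linear_model_json <- function(model, path) {
  jsonlite::write_json(list(
    metric = model$metric, with_activity = model$with_activity,
    coefficients = as.list(model$coefficients),
    activities = model$activities, r2 = model$r2,
    residual_sd = model$residual_sd, n = model$n
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
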