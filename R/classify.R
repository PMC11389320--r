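# Five-class activity classification from 4-s epochs with a hybrid
# CNN-BiLSTM: two 1-d convolution blocks (ReLU, max-pool) extract local
# waveform features, a bidirectional LSTM over the pooled feature sequence
# captures temporal structure in both directions, and a dense softmax head
# emits class probabilities.

#' Build an untrained activity classifier
#'
#' Default architecture: conv(16 filters, kernel 5, ReLU, max-pool 4) ->
#' conv(32, kernel 5, ReLU, max-pool 4) -> bidirectional LSTM (24 units
#' per direction, final states) -> dense softmax over the five classes.
#' The input contract is exactly 400 x 3 (4 s at 100 Hz); configs
#' requesting anything else are rejected. Weight initialisation is
#' deterministic given `seed`.
#'
#' @param config Pipeline configuration (`$classifier` section).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `"catse_classifier"`.
#' @export
build_classifier <- function(config = default_config(), seed = 1L) {
  cc <- config$classifier
  input_shape <- c(config$epoch_s * config$sample_rate_hz, 3L)
  if (!identical(as.integer(input_shape), c(400L, 3L))) {
    stop("classifier input contract is 400 x 3; got ",
         paste(input_shape, collapse = " x "))
  }
  k <- cc$conv_kernel; f1 <- cc$conv_filters[1]; f2 <- cc$conv_filters[2]
  H <- cc$lstm_units; p <- cc$pool
  if (400 %% (p * p) != 0) stop("pool factor must divide the window twice")
  with_seed(seed, {
    params <- list(
      W1 = glorot_uniform(k * 3, f1), b1 = numeric(f1),
      W2 = glorot_uniform(k * f1, f2), b2 = numeric(f2),
      Wf = glorot_uniform(f2 + H, 4 * H), bf = lstm_bias(H),
      Wb = glorot_uniform(f2 + H, 4 * H), bb = lstm_bias(H),
      Wd = glorot_uniform(2 * H, 5), bd = numeric(5)
    )
    structure(list(
      params = params,
      config = cc,
      labels = activity_levels(),
      input_shape = input_shape,
      seed = seed,
      trained = FALSE,
      history = NULL,
      config_hash = config_hash(cc)
    ), class = "catse_classifier")
  })
}

# forget-gate bias of 1 (standard LSTM initialisation)
lstm_bias <- function(H) c(numeric(H), rep(1, H), numeric(2 * H))

# cheap deterministic hash of a config subtree (md5 of its deparse)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}

#' @export
print.catse_classifier <- function(x, ...) {
  cc <- x$config
  cat(sprintf(
    "<catse_classifier> conv %s (k=%d) -> BiLSTM %d/dir -> softmax(5); %s\n",
    paste(cc$conv_filters, collapse = "/"), cc$conv_kernel, cc$lstm_units,
    if (x$trained) "trained" else "untrained"
  ))
  invisible(x)
}

# full forward pass; returns logits plus caches for backprop
classifier_forward <- function(params, X, pool, dropout = 0, training = FALSE) {
  c1 <- conv1d_forward(X, params$W1, params$b1)
  r1 <- relu_forward(c1$out)
  p1 <- maxpool_forward(r1$out, pool)
  c2 <- conv1d_forward(p1$out, params$W2, params$b2)
  r2 <- relu_forward(c2$out)
  p2 <- maxpool_forward(r2$out, pool)
  lf <- lstm_forward(p2$out, params$Wf, params$bf)
  lb <- lstm_forward(p2$out, params$Wb, params$bb, reverse = TRUE)
  h <- cbind(lf$h, lb$h)
  mask <- NULL
  if (training && dropout > 0) {
    mask <- matrix(stats::runif(length(h)) >= dropout, nrow(h)) / (1 - dropout)
    h <- h * mask
  }
  dn <- dense_forward(h, params$Wd, params$bd)
  list(logits = dn$out,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    lf = lf, lb = lb, dn = dn, mask = mask))
}

classifier_backward <- function(params, dlogits, cache) {
  H <- ncol(params$Wd) * 0 + ncol(params$Wf) / 4
  dd <- dense_backward(dlogits, params$Wd, cache$dn$cache)
  dh <- dd$dX
  if (!is.null(cache$mask)) dh <- dh * cache$mask
  dlf <- lstm_backward(dh[, 1:H, drop = FALSE], params$Wf, cache$lf$cache)
  dlb <- lstm_backward(dh[, (H + 1):(2 * H), drop = FALSE], params$Wb, cache$lb$cache)
  dp2 <- dlf$dX + dlb$dX
  dr2 <- maxpool_backward(dp2, cache$p2$cache)
  dc2 <- relu_backward(dr2, cache$r2$cache)
  bc2 <- conv1d_backward(dc2, params$W2, cache$c2$cache)
  dp1 <- maxpool_backward(bc2$dX, cache$p1$cache)
  dc1 <- relu_backward(dp1, cache$r1$cache)
  bc1 <- conv1d_backward(dc1, params$W1, cache$c1$cache)
  list(W1 = bc1$dW, b1 = bc1$db, W2 = bc2$dW, b2 = bc2$db,
       Wf = dlf$dW, bf = dlf$db, Wb = dlb$dW, bb = dlb$db,
       Wd = dd$dW, bd = dd$db)
}

# one-hot encode labels against the frozen coding
one_hot <- function(labels, levels) {
  m <- matrix(0, length(labels), length(levels))
  m[cbind(seq_along(labels), match(labels, levels))] <- 1
  m
}

# mean cross-entropy of a window array under given params, in batches
classifier_loss <- function(params, X, Y, pool, batch = 256L) {
  n <- dim(X)[1]
  tot <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    fw <- classifier_forward(params, X[s:e, , , drop = FALSE], pool)
    tot <- tot + softmax_xent(fw$logits, Y[s:e, , drop = FALSE])$loss * (e - s + 1)
  }
  tot / n
}

#' Train the activity classifier
#'
#' Minimises categorical cross-entropy with Adam. The train/validation
#' split is per participant (never per epoch), so no individual
#' contributes to both sides; the weights with the best validation loss
#' are retained. Training is deterministic given `seed`.
#'
#' @param model A [build_classifier()] model.
#' @param epochs An [epoch_set()] whose `info` has `true_label` and,
#'   for the subject-wise split, a `participant` column.
#' @param config Pipeline configuration.
#' @param seed Integer seed for shuffling (and dropout, if enabled).
#' @return The trained model, with a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_classifier <- function(model, epochs, config = default_config(),
                             seed = 1L) {
  cc <- config$classifier
  info <- epochs$info
  keep <- !is.na(info$true_label)
  if (length(unique(info$true_label[keep])) < 2) {
    stop("training requires at least 2 activity classes")
  }
  bad <- setdiff(unique(info$true_label[keep]), model$labels)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  X <- epochs$windows[keep, , , drop = FALSE]
  Y <- one_hot(info$true_label[keep], model$labels)
  part <- if ("participant" %in% names(info)) info$participant[keep] else NULL

  with_seed(seed, {
    n <- dim(X)[1]
    if (!is.null(part) && length(unique(part)) >= 2) {
      ids <- unique(part)
      n_val <- max(1L, round(cc$val_fraction * length(ids)))
      val_ids <- sample(ids, n_val)
      val <- part %in% val_ids
    } else {
      if (!is.null(part)) {
        warning("single participant; falling back to a random epoch split")
      } else {
        warning("no participant column; falling back to a random epoch split")
      }
      val <- seq_len(n) %in% sample.int(n, max(1L, round(cc$val_fraction * n)))
    }
    Xtr <- X[!val, , , drop = FALSE]; Ytr <- Y[!val, , drop = FALSE]
    Xva <- X[val, , , drop = FALSE]; Yva <- Y[val, , drop = FALSE]

    params <- model$params
    state <- adam_init(params)
    best <- list(loss = Inf, params = params)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    wait <- 0L
    for (ep in seq_len(cc$n_epochs)) {
      tr_loss <- 0
      for (b in minibatches(dim(Xtr)[1], cc$batch_size)) {
        fw <- classifier_forward(params, Xtr[b, , , drop = FALSE], cc$pool,
                                 cc$dropout, training = TRUE)
        ls <- softmax_xent(fw$logits, Ytr[b, , drop = FALSE])
        grads <- classifier_backward(params, ls$dlogits, fw$cache)
        upd <- adam_step(params, grads, state, lr = cc$learning_rate)
        params <- upd$params; state <- upd$state
        tr_loss <- tr_loss + ls$loss * length(b)
      }
      tr_loss <- tr_loss / dim(Xtr)[1]
      va_loss <- classifier_loss(params, Xva, Yva, cc$pool)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                     val_loss = va_loss))
      if (va_loss < best$loss) {
        best <- list(loss = va_loss, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cc$patience) break
      }
    }
    model$params <- best$params
    model$trained <- TRUE
    model$history <- hist
    model$val_loss <- best$loss
    model
  })
}

#' Predict activity classes for epochs
#'
#' Fills `predicted_label` (argmax of the class probabilities; ties break
#' towards the lowest class code) and attaches the `n x 5` probability
#' matrix.
#'
#' @param model A trained classifier.
#' @param epochs An [epoch_set()].
#' @param batch Forward-pass batch size.
#' @return The epoch set with `probs` and `info$predicted_label` filled.
#' @export
predict_activities <- function(model, epochs, batch = 256L) {
  if (!model$trained) stop("classifier has not been trained")
  X <- epochs$windows
  d <- dim(X)
  if (length(d) != 3 || d[2] != model$input_shape[1] || d[3] != 3) {
    stop("epoch windows must be ", model$input_shape[1], " x 3")
  }
  bad <- which(apply(X, 1, function(w) any(!is.finite(w))))
  if (length(bad)) stop("non-finite window at epoch index ", bad[1])
  n <- d[1]
  probs <- matrix(NA_real_, n, 5)
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    fw <- classifier_forward(model$params, X[s:e, , , drop = FALSE],
                             model$config$pool)
    probs[s:e, ] <- softmax_rows(fw$logits)
  }
  colnames(probs) <- paste0("p_", model$labels)
  epochs$probs <- probs
  epochs$info$predicted_label <- model$labels[max.col(probs, ties.method = "first")]
  epochs
}

#' Majority-filter predicted labels
#'
#' Optional post-classification smoothing (off by default in the
#' pipeline): each epoch's label is replaced by the modal label in a
#' centred window of `k` epochs, with ties keeping the original label.
#'
#' @param epochs A classified [epoch_set()].
#' @param k Odd window length (default 3).
#' @return The epoch set with smoothed `predicted_label`.
#' @export
smooth_predictions <- function(epochs, k = 3) {
  stopifnot(k %% 2 == 1)
  lab <- epochs$info$predicted_label
  n <- length(lab)
  half <- (k - 1) / 2
  out <- lab
  for (i in seq_len(n)) {
    w <- lab[max(1, i - half):min(n, i + half)]
    tab <- table(w)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) out[i] <- top
  }
  epochs$info$predicted_label <- out
  epochs
}

#' Group classified epochs into contiguous activity sequences
#'
#' Maximal runs of identical labels, with sample spans into the source
#' recording. All five activities are grouped; stride segmentation
#' downstream only consumes the walking/running/cycling rows.
#'
#' @param epochs A classified [epoch_set()] (or any epoch set, via
#'   `label_col`).
#' @param label_col Which label column to group on
#'   (default `"predicted_label"`).
#' @param config Pipeline configuration (for the epoch length).
#' @return Data frame with columns `activity`, `first_epoch`,
#'   `last_epoch` (1-based epoch rows), `start_sample`, `end_sample`
#'   (1-based, inclusive), `n_epochs`.
#' @export
group_sequences <- function(epochs, label_col = "predicted_label",
                            config = default_config()) {
  lab <- epochs$info[[label_col]]
  if (all(is.na(lab))) stop("no labels in column ", label_col)
  L <- as.integer(config$epoch_s * config$sample_rate_hz)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    activity = r$values,
    first_epoch = starts,
    last_epoch = ends,
    start_sample = (starts - 1L) * L + 1L,
    end_sample = ends * L,
    n_epochs = r$lengths,
    stringsAsFactors = FALSE
  )
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint carries the weights, the frozen label coding and the
#' config hash, so a loaded model refuses nothing silently.
#'
#' @param model A classifier or TCN model object.
#' @param path Checkpoint path (RDS).
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  m <- readRDS(path)
  if (!inherits(m, c("catse_classifier", "tcn_ee_model"))) {
    stop("not a recognised model checkpoint: ", path)
  }
  m
}

#' Write classified epochs to CSV
#'
#' Columns: epoch_index, start_s, predicted_label, p_sitting ... p_cycling.
#'
#' @param epochs A classified [epoch_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_csv <- function(epochs, path) {
  df <- data.frame(epoch_index = epochs$info$index,
                   start_s = epochs$info$start_time,
                   predicted_label = epochs$info$predicted_label)
  if (!is.null(epochs$probs)) df <- cbind(df, as.data.frame(epochs$probs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
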