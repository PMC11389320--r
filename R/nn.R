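# Minimal neural-network engine used by the activity classifier
# (CNN-BiLSTM) and the stride energy-expenditure model (TCN).
#
# Batches are 3-d arrays [B, T, C] (batch, time, channels). Convolutions
# are implemented by im2col + matrix multiplication; weights for a 1-d
# convolution with kernel k over C channels producing F filters are stored
# as a (k*C) x F matrix. All layers provide exact analytic gradients,
# verified against finite differences in the test suite.

# ---- initialisation --------------------------------------------------------

glorot_uniform <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# ---- 1-d convolution -------------------------------------------------------

# per-tap time offsets for "same" (centred) or "causal" (past-only) padding
conv_offsets <- function(k, dilation, pad) {
  if (pad == "same") {
    ((seq_len(k) - 1) - (k - 1) %/% 2) * dilation
  } else {
    ((seq_len(k) - 1) - (k - 1)) * dilation
  }
}

# build the (B*T) x (k*C) im2col matrix; row order is (t-1)*B + b
conv_im2col <- function(X, k, dilation, pad) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  off <- conv_offsets(k, dilation, pad)
  Xcol <- matrix(0, B * T, k * C)
  for (j in seq_len(k)) {
    o <- off[j]
    t_lo <- max(1L, 1L - o); t_hi <- min(T, T - o)
    if (t_lo > t_hi) next
    tset <- t_lo:t_hi
    rows <- as.vector(outer(seq_len(B), (tset - 1L) * B, `+`))
    src <- X[, tset + o, , drop = FALSE]
    Xcol[rows, ((j - 1L) * C + 1L):(j * C)] <- matrix(src, length(tset) * B, C)
  }
  Xcol
}

conv1d_forward <- function(X, W, b, dilation = 1L, pad = "same") {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  k <- nrow(W) / C
  Xcol <- conv_im2col(X, k, dilation, pad)
  Y <- sweep(Xcol %*% W, 2, b, `+`)
  list(out = array(Y, c(B, T, ncol(W))),
       cache = list(Xcol = Xcol, dims = d, k = k, dilation = dilation, pad = pad))
}

conv1d_backward <- function(dY, W, cache) {
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]
  dYmat <- matrix(dY, B * T, ncol(W))
  dW <- crossprod(cache$Xcol, dYmat)
  db <- colSums(dYmat)
  dXcol <- tcrossprod(dYmat, W)
  dX <- array(0, d)
  off <- conv_offsets(cache$k, cache$dilation, cache$pad)
  for (j in seq_len(cache$k)) {
    o <- off[j]
    t_lo <- max(1L, 1L - o); t_hi <- min(T, T - o)
    if (t_lo > t_hi) next
    tset <- t_lo:t_hi
    rows <- as.vector(outer(seq_len(B), (tset - 1L) * B, `+`))
    piece <- array(dXcol[rows, ((j - 1L) * C + 1L):(j * C)],
                   c(B, length(tset), C))
    dX[, tset + o, ] <- dX[, tset + o, , drop = FALSE] + piece
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- ReLU and pooling ------------------------------------------------------

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_backward <- function(dY, mask) dY * mask

# non-overlapping max pooling by factor p along time (T divisible by p)
maxpool_forward <- function(X, p) {
  d <- dim(X); T <- d[2]
  stopifnot(T %% p == 0)
  M <- X[, seq(1L, T, by = p), , drop = FALSE]
  arg <- array(1L, dim(M))
  if (p > 1) {
    for (i in 2:p) {
      S <- X[, seq(i, T, by = p), , drop = FALSE]
      upd <- S > M
      M[upd] <- S[upd]
      arg[upd] <- i
    }
  }
  list(out = M, cache = list(arg = arg, p = p, dims = d))
}

maxpool_backward <- function(dY, cache) {
  dX <- array(0, cache$dims)
  T <- cache$dims[2]; p <- cache$p
  for (i in seq_len(p)) {
    mask <- cache$arg == i
    slice <- array(0, dim(dY))
    slice[mask] <- dY[mask]
    dX[, seq(i, T, by = p), ] <- slice
  }
  dX
}

# ---- dense -----------------------------------------------------------------

dense_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, `+`), cache = X)
}

dense_backward <- function(dY, W, cache) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache, dY), db = colSums(dY))
}

# ---- LSTM ------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# batched LSTM over X [B,T,C]; W is (C+H) x 4H with gate order i,f,o,g.
# Returns the final hidden state (the only output the models use).
lstm_forward <- function(X, W, b, reverse = FALSE) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  H <- ncol(W) / 4
  torder <- if (reverse) T:1 else 1:T
  h <- matrix(0, B, H); cs <- matrix(0, B, H)
  cache <- vector("list", T)
  for (step in seq_len(T)) {
    t <- torder[step]
    xh <- cbind(matrix(X[, t, ], B, C), h)
    z <- sweep(xh %*% W, 2, b, `+`)
    i_g <- sigmoid(z[, 1:H, drop = FALSE])
    f_g <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o_g <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g_g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cs
    cs <- f_g * c_prev + i_g * g_g
    tc <- tanh(cs)
    h <- o_g * tc
    cache[[step]] <- list(xh = xh, i = i_g, f = f_g, o = o_g, g = g_g,
                          c_prev = c_prev, tc = tc)
  }
  list(h = h, cache = list(steps = cache, dims = d, H = H, torder = torder))
}

# backward from the gradient of the final hidden state only
lstm_backward <- function(dh_T, W, cache) {
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]; H <- cache$H
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(ncol(W))
  dX <- array(0, d)
  dh <- dh_T; dc <- matrix(0, B, H)
  for (step in T:1) {
    s <- cache$steps[[step]]
    t <- cache$torder[step]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dc <- dc * s$f
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                do * s$o * (1 - s$o),
                dg * (1 - s$g^2))
    dW <- dW + crossprod(s$xh, dz)
    db <- db + colSums(dz)
    dxh <- tcrossprod(dz, W)
    dX[, t, ] <- dxh[, 1:C, drop = FALSE]
    dh <- dxh[, (C + 1):(C + H), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- losses ----------------------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# categorical cross-entropy; Y is a one-hot matrix. Returns loss and the
# gradient wrt logits (already divided by batch size).
softmax_xent <- function(logits, Y) {
  P <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(rowSums(Y * log(P + eps)))
  list(loss = loss, dlogits = (P - Y) / nrow(Y), probs = P)
}

mse_loss <- function(pred, y) {
  d <- pred - y
  list(loss = mean(d^2), dpred = 2 * d / length(y))
}

# ---- Adam optimiser --------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# accumulate two gradient lists
grad_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# deterministic minibatch index generator
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
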