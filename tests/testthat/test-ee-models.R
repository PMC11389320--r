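test_that("ENMO and MAD reproduce closed-form hand values", {
  L <- 400
  # static 1 g -> ENMO 0, MAD 0
  w <- cbind(rep(1, L), 0, 0)
  expect_equal(compute_enmo(w), 0, tolerance = 1e-12)
  expect_equal(compute_mad(w), 0, tolerance = 1e-12)
  # constant magnitude 1.2 -> ENMO 0.2
  expect_equal(compute_enmo(cbind(rep(1.2, L), 0, 0)), 0.2, tolerance = 1e-12)
  # half at 0.8, half at 1.4: negatives truncated -> mean(0, 0.4)/2 = 0.2
  w2 <- cbind(c(rep(0.8, L / 2), rep(1.4, L / 2)), 0, 0)
  expect_equal(compute_enmo(w2), 0.2, tolerance = 1e-12)
  # magnitudes alternating 0.9/1.1 -> MAD 0.1
  w3 <- cbind(rep(c(0.9, 1.1), L / 2), 0, 0)
  expect_equal(compute_mad(w3), 0.1, tolerance = 1e-12)
  # magnitudes (1, 1, 1, 1.4) repeated -> MAD 0.15
  w4 <- cbind(rep(c(1, 1, 1, 1.4), L / 4), 0, 0)
  expect_equal(compute_mad(w4), 0.15, tolerance = 1e-12)
  expect_error(compute_enmo(cbind(NA, 1, 1)), "non-finite")
})

test_that("ENMO and MAD are axis-permutation invariant", {
  set.seed(31)
  w <- matrix(rnorm(400 * 3, 0, 0.5), 400, 3)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(compute_enmo(w[, perm]), compute_enmo(w), tolerance = 1e-12)
    expect_equal(compute_mad(w[, perm]), compute_mad(w), tolerance = 1e-12)
  }
  expect_gte(compute_enmo(w), 0)
  expect_gte(compute_mad(w), 0)
})

test_that("linear EE models recover known coefficients", {
  set.seed(32)
  n <- 1000
  enmo <- runif(n, 0, 0.3)
  ee <- 0.02 + 0.5 * enmo + rnorm(n, 0, 1e-4)
  fit <- fit_linear_ee(data.frame(ee = ee, enmo = enmo), "enmo")
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 0.02) / 0.02, 0.05)
  expect_lt(abs(fit$coefficients[["m"]] - 0.5) / 0.5, 0.05)
  # noiseless data: R2 = 1
  fit0 <- fit_linear_ee(data.frame(ee = 0.01 + 0.4 * enmo, enmo = enmo), "enmo")
  expect_equal(fit0$r2, 1, tolerance = 1e-9)
  # hand prediction: intercept 0.01, slope 0.4, ENMO 0.1 -> 0.05
  expect_equal(as.numeric(predict_linear_ee(fit0, 0.1)), 0.05, tolerance = 1e-9)
  expect_error(fit_linear_ee(data.frame(ee = 1:5, enmo = 1:5), "enmo"),
               "10 observations")
})

test_that("activity terms require multiple activities and known levels", {
  set.seed(33)
  df <- data.frame(ee = runif(40, 0.02, 0.2), enmo = runif(40, 0, 0.3),
                   activity = rep(c("sitting", "walking"), each = 20))
  fit <- fit_linear_ee(df, "enmo", with_activity = TRUE)
  expect_identical(fit$activities, c("sitting", "walking"))
  # unseen activity level rejected
  expect_error(predict_linear_ee(fit, 0.1, "cycling"), "not seen")
  # single-activity data rejected
  expect_error(fit_linear_ee(df[df$activity == "sitting", ], "enmo", TRUE),
               ">= 2 activities")
  # interaction model is affine in the metric per activity
  p1 <- predict_linear_ee(fit, c(0.1, 0.2, 0.3), rep("walking", 3))
  expect_equal(diff(as.numeric(p1)), rep(diff(as.numeric(p1))[1], 2),
               tolerance = 1e-9)
})

test_that("negative linear predictions are floored at zero and flagged", {
  df <- data.frame(ee = seq(0.001, 0.02, length.out = 20),
                   enmo = seq(0, 0.3, length.out = 20))
  fit <- fit_linear_ee(df, "enmo")
  p <- predict_linear_ee(fit, -5)   # far below the data -> negative affine value
  expect_equal(as.numeric(p), 0)
  expect_identical(attr(p, "n_truncated"), 1L)
})

test_that("TCN honours its I/O contract and trains deterministically", {
  cfg <- default_config(tcn = list(n_epochs = 2L, filters = 8L))
  m <- build_tcn_ee(cfg, seed = 9)
  # same seed -> identical initial weights
  m2 <- build_tcn_ee(cfg, seed = 9)
  expect_identical(m$params, m2$params)

  set.seed(34)
  n <- 60
  shapes <- array(rnorm(n * 30 * 3, 0, 0.5), c(n, 30, 3))
  amp <- apply(shapes, 1, function(s) mean(abs(s)))
  info <- data.frame(activity = rep(c("walking", "running"), n / 2),
                     ref_ee = 0.05 + 0.1 * amp,
                     participant = rep(c("A", "B", "C"), each = n / 3))
  st <- stride_set(info, shapes)
  t1 <- train_tcn_ee(m, st, cfg, seed = 4)
  t2 <- train_tcn_ee(m, st, cfg, seed = 4)
  expect_identical(t1$val_loss, t2$val_loss)
  p <- predict_stride_ee(t1, st)
  expect_length(p, n)
  expect_true(all(is.finite(p)) && all(p >= 0))
  # duplicate stride input -> identical outputs
  expect_identical(p[1], predict_stride_ee(t1, stride_set(info[c(1, 1), ],
                                                          shapes[c(1, 1), , , drop = FALSE]))[1])
  # activities outside the gait vocabulary are rejected
  bad <- st; bad$info$activity[1] <- "sitting"
  expect_error(predict_stride_ee(t1, bad), "walking/running/cycling")
})

# a hand-crafted TCN whose prediction equals the mean of the stride's first
# acceleration channel (all convolutions zeroed, identity skip, pass-through
# head) -- lets composite routing be checked against hand arithmetic
passthrough_tcn <- function() {
  cfg <- default_config()
  m <- build_tcn_ee(cfg, seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  m$params$Ws[1, 1] <- 1
  m$params$Wd1[1, 1] <- 1
  m$params$Wd2[1, 1] <- 1
  m$trained <- TRUE
  m$y_mean <- 0; m$y_sd <- 1
  m
}

test_that("composite assembly routes epochs per the documented rules", {
  cfg <- default_config()
  # three epochs: sitting, walking (with strides), running (no strides)
  L <- 400
  windows <- array(0, c(3, L, 3))
  windows[1, , 3] <- -1
  info <- data.frame(index = 0:2, start_time = c(0, 4, 8),
                     true_label = c("sitting", "walking", "running"),
                     predicted_label = c("sitting", "walking", "running"))
  ep <- epoch_set(windows, info)
  ep <- compute_epoch_metrics(ep)

  # two walking strides overlapping epoch 2 with constant x levels 0.06/0.08
  shapes <- array(0, c(2, 30, 3))
  shapes[1, , 1] <- 0.06
  shapes[2, , 1] <- 0.08
  st <- stride_set(data.frame(activity = "walking",
                              start_sample = c(401L, 601L),
                              end_sample = c(601L, 801L),
                              duration_s = c(2, 2)), shapes)
  tcn <- passthrough_tcn()
  lin <- fit_linear_ee(data.frame(
    ee = c(seq(0.017, 0.019, length.out = 10), seq(0.05, 0.2, length.out = 10),
           seq(0.08, 0.25, length.out = 10)),
    enmo = c(seq(0, 0.004, length.out = 10), seq(0.01, 0.3, length.out = 10),
             seq(0.02, 0.4, length.out = 10)),
    activity = rep(c("sitting", "walking", "running"), each = 10)),
    "enmo", with_activity = TRUE)

  out <- compose_catse3(ep, st, tcn, lin, cfg)
  expect_identical(nrow(out), 3L)
  expect_identical(out$source, c("regression", "stride_model", "fallback"))
  # mean of the two overlapping stride predictions: (0.06 + 0.08) / 2
  expect_equal(out$ee_kcal_kg_min[2], 0.07, tolerance = 1e-9)
  expect_true(all(out$ee_kcal_kg_min >= 0))

  # all-sitting input -> every record from the regression
  ep_sit <- ep
  ep_sit$info$predicted_label <- rep("sitting", 3)
  out2 <- compose_catse3(ep_sit, stride_set(st$info[0, ], st$shapes[0, , , drop = FALSE]),
                         tcn, lin, cfg)
  expect_true(all(out2$source == "regression"))

  # missing components are named
  expect_error(compose_catse3(ep, st, NULL, lin), "stride EE model")
  expect_error(compose_catse3(ep, st, tcn, NULL), "regression")
  lin_simple <- fit_linear_ee(data.frame(ee = runif(20, 0, 1), enmo = runif(20)),
                              "enmo")
  expect_error(compose_catse3(ep, st, tcn, lin_simple), "activity type")
})
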