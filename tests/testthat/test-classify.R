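test_that("the classifier honours its input/output contract", {
  m <- build_classifier(seed = 2)
  # same seed -> identical initial weights
  expect_identical(m$params, build_classifier(seed = 2)$params)
  expect_false(identical(m$params, build_classifier(seed = 3)$params))
  # non-400-sample windows are rejected by construction
  expect_error(build_classifier(default_config(epoch_s = 5)), "400 x 3")

  # a batch of k windows yields k probability vectors summing to 1
  mt <- m; mt$trained <- TRUE
  set.seed(41)
  ep <- epoch_set(array(rnorm(4 * 400 * 3, 0, 0.5), c(4, 400, 3)),
                  data.frame(index = 0:3, start_time = (0:3) * 4,
                             true_label = NA_character_,
                             predicted_label = NA_character_))
  out <- predict_activities(mt, ep)
  expect_identical(dim(out$probs), c(4L, 5L))
  expect_equal(rowSums(out$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(out$probs >= 0))
  expect_true(all(out$info$predicted_label %in% activity_levels()))
})

test_that("exact probability ties break towards the lowest class code", {
  # all-zero weights emit uniform probabilities for any input
  m <- build_classifier(seed = 2)
  m$params <- lapply(m$params, function(p) p * 0)
  m$trained <- TRUE
  ep <- epoch_set(array(0.3, c(2, 400, 3)),
                  data.frame(index = 0:1, start_time = c(0, 4),
                             true_label = NA_character_,
                             predicted_label = NA_character_))
  out <- predict_activities(m, ep)
  expect_equal(out$probs[1, ], rep(0.2, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(out$info$predicted_label, c("sitting", "sitting"))
})

test_that("training separates synthetic classes and is seed-deterministic", {
  cfg <- default_config(classifier = list(n_epochs = 40L, patience = 10L))
  # four participants, a few windows per class each
  windows <- list(); labels <- character(0); parts <- character(0)
  acts <- list(c("sitting", NA), c("standing", NA), c("walking", 3.7),
               c("running", 9), c("cycling", 90))
  for (i in 1:4) {
    p <- synthetic_participant(paste0("C", i), 500 + i)
    for (a in acts) {
      b <- simulate_bout(p, a[1], as.numeric(a[2]), 1, 24, seed = i * 10)
      ep <- make_epochs(b$recording)
      windows[[length(windows) + 1]] <- ep$windows
      labels <- c(labels, rep(a[1], length(ep)))
      parts <- c(parts, rep(paste0("C", i), length(ep)))
    }
  }
  allw <- array(0, c(length(labels), 400, 3))
  at <- 1
  for (w in windows) {
    allw[at:(at + dim(w)[1] - 1), , ] <- w
    at <- at + dim(w)[1]
  }
  ep_all <- epoch_set(allw, data.frame(index = seq_along(labels) - 1L,
                                       start_time = 0,
                                       true_label = labels,
                                       predicted_label = NA_character_,
                                       participant = parts))
  m <- build_classifier(cfg, seed = 7)
  tr <- train_classifier(m, ep_all, cfg, seed = 7)
  expect_true(tr$trained)
  # the retained checkpoint is at least as good as the first epoch
  expect_lte(tr$val_loss, tr$history$val_loss[1])
  # determinism: identical seed/config/data -> identical validation loss
  tr2 <- train_classifier(m, ep_all, cfg, seed = 7)
  expect_identical(tr$val_loss, tr2$val_loss)
  # high accuracy on its own (separable) training pool
  pred <- predict_activities(tr, ep_all)
  acc <- mean(pred$info$predicted_label == labels)
  expect_gte(acc, 0.9)
  # single-class input is rejected
  sit_only <- epoch_set(allw[labels == "sitting", , , drop = FALSE],
                        data.frame(index = 0:(sum(labels == "sitting") - 1),
                                   start_time = 0, true_label = "sitting",
                                   predicted_label = NA_character_))
  expect_error(train_classifier(m, sit_only, cfg), "2 activity classes")
})

test_that("sequence grouping returns maximal runs covering every epoch", {
  mk_ep <- function(labs) {
    n <- length(labs)
    epoch_set(array(0, c(n, 400, 3)),
              data.frame(index = seq_len(n) - 1L, start_time = (seq_len(n) - 1) * 4,
                         true_label = NA_character_, predicted_label = labs))
  }
  s <- group_sequences(mk_ep(c("walking", "walking", "running", "running", "running")))
  expect_identical(nrow(s), 2L)
  expect_identical(s$n_epochs, c(2L, 3L))
  expect_identical(s$start_sample, c(1L, 801L))
  expect_identical(s$end_sample, c(800L, 2000L))
  # singleton
  expect_identical(nrow(group_sequences(mk_ep("sitting"))), 1L)
  # alternating labels -> three maximal runs
  expect_identical(nrow(group_sequences(mk_ep(c("walking", "running", "walking")))), 3L)
  # coverage: epochs partition exactly once
  s3 <- group_sequences(mk_ep(c("sitting", "sitting", "walking", "sitting")))
  expect_identical(sum(s3$n_epochs), 4L)
  expect_true(all(s3$first_epoch[-1] == s3$last_epoch[-nrow(s3)] + 1L))
})

test_that("label smoothing is majority vote with tie protection", {
  ep <- epoch_set(array(0, c(5, 400, 3)),
                  data.frame(index = 0:4, start_time = (0:4) * 4,
                             true_label = NA_character_,
                             predicted_label = c("walking", "walking", "running",
                                                 "walking", "walking")))
  sm <- smooth_predictions(ep, 3)
  expect_identical(sm$info$predicted_label, rep("walking", 5))
})

test_that("model checkpoints round-trip with label coding intact", {
  m <- build_classifier(seed = 11)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$labels, activity_levels())
  expect_identical(m2$params, m$params)
  expect_identical(m2$config_hash, m$config_hash)
  expect_error(load_model(tempfile()), "not found")
})
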