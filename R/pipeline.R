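# Pipeline orchestration: the end-to-end chain on one recording
# (preprocess -> classify -> group -> stride-segment -> compose) and the
# full synthetic train/test experiment.

#' Run the full estimation pipeline on one recording
#'
#' Executes preprocessing, epoching, activity classification, sequence
#' grouping, stride segmentation and composite assembly, logging record
#' counts per stage. The output rows cover every epoch exactly once.
#'
#' @param raw Path to a raw-acceleration CSV or a [raw_recording()].
#' @param classifier A trained [build_classifier()] model (or checkpoint
#'   path).
#' @param tcn_model A trained [build_tcn_ee()] model (or checkpoint path).
#' @param linear_model A fitted ENMO + activity [fit_linear_ee()] model.
#' @param config Pipeline configuration.
#' @param out_csv Optional path for the EE time-series CSV.
#' @param quiet Suppress stage logging.
#' @return An `ee_timeseries` data frame with a `counts` attribute
#'   (epochs, sequences, strides, fallbacks).
#' @export
run_pipeline <- function(raw, classifier, tcn_model, linear_model,
                         config = default_config(), out_csv = NULL,
                         quiet = FALSE) {
  log_ <- function(...) if (!quiet) message("[pipeline] ", sprintf(...))
  rec <- if (inherits(raw, "raw_recording")) raw else read_raw_csv(raw)
  if (is.character(classifier)) classifier <- load_model(classifier)
  if (is.character(tcn_model)) tcn_model <- load_model(tcn_model)

  pp <- preprocess_recording(rec, config, quiet = TRUE)
  log_("preprocessed %d samples (calibration %s)", nrow(pp$recording$acc),
       if (pp$calibration$failed) "identity" else "estimated")
  epochs <- make_epochs(pp$recording, config = config)
  if (length(epochs) == 0) stop("stage epoching: recording shorter than one epoch")
  epochs <- compute_epoch_metrics(epochs)
  log_("%d epochs", length(epochs))
  epochs <- predict_activities(classifier, epochs)
  sequences <- group_sequences(epochs, config = config)
  log_("%d activity sequences", nrow(sequences))
  strides <- segment_sequences(pp$recording$acc, sequences, config$sample_rate_hz,
                               config)
  log_("%d strides (%d rejected)", nrow(strides$info), strides$n_rejected)
  out <- compose_catse3(epochs, strides, tcn_model, linear_model, config)
  counts <- c(epochs = length(epochs), sequences = nrow(sequences),
              strides = nrow(strides$info),
              fallbacks = sum(out$source == "fallback"))
  log_("composed %d epochs (%d fallback)", counts["epochs"], counts["fallbacks"])
  attr(out, "counts") <- counts
  if (!is.null(out_csv)) write_ee_csv(out, out_csv)
  out
}

# process one simulated bout into the compact artifacts the experiment
# keeps: labelled epochs with metrics, steady-state reference EE, and
# ground-truth stride segmentation
process_bout <- function(bout, breaths, config) {
  pp <- preprocess_recording(bout$recording, config, quiet = TRUE)
  rec <- pp$recording
  labels <- data.frame(start_s = 0, end_s = bout$duration_s,
                       activity = bout$activity)
  epochs <- make_epochs(rec, labels, config)
  epochs <- compute_epoch_metrics(epochs)
  ref <- steady_state_ee(breaths, c(0, bout$duration_s), bout$mass_kg,
                         config = config)
  gait <- bout$activity %in% c("walking", "running", "cycling")
  strides <- NULL
  n_peaks <- 0L
  cadence <- NA_real_
  if (gait) {
    sig <- select_stride_signal(rec$acc, bout$activity, rec$sample_rate, config)
    peaks <- suppressWarnings(
      detect_stride_peaks(sig, bout$activity, rec$sample_rate, config))
    n_peaks <- length(peaks)
    if (n_peaks >= 2) {
      cadence <- (n_peaks - 1) / ((peaks[n_peaks] - peaks[1]) / rec$sample_rate)
    }
    strides <- suppressWarnings(
      extract_strides(rec$acc, peaks, bout$activity, rec$sample_rate, config))
  }
  list(recording = rec, epochs = epochs, ref_ee = ref$ee, strides = strides,
       n_detected_strides = max(n_peaks - 1L, 0L), cadence = cadence)
}

#' Run the synthetic train/test experiment
#'
#' Simulates the full activity protocol for `n_participants`, trains the
#' activity classifier, the four linear baselines and the stride EE model
#' on the training participants, and evaluates the classifier and all
#' five EE models (CATSE3, ENMO, MAD, ENMO + activity, MAD + activity)
#' on the held-out test participants. Classifier training uses a
#' subsample of windows per bout and the TCN a subsample of strides per
#' bout (config `$experiment`); evaluation uses every test epoch.
#' Deterministic given the configured seed.
#'
#' @param config Pipeline configuration; `config$experiment` controls
#'   sizes, split and seed. Optional `train_ids` / `test_ids` override
#'   the default split (last `n_test` participants) and must be disjoint.
#' @param quiet Suppress progress logging.
#' @return An object of class `"catse3_experiment"` with the trained
#'   models, the classification report, per-model regression reports, a
#'   comparison table, stride-recovery summary and the test predictions.
#' @export
run_experiment <- function(config = default_config(), quiet = FALSE) {
  ec <- config$experiment
  log_ <- function(...) if (!quiet) message("[experiment] ", sprintf(...))
  n <- ec$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  test_ids <- if (!is.null(ec$test_ids)) ec$test_ids else ids[(n - ec$n_test + 1):n]
  train_ids <- if (!is.null(ec$train_ids)) ec$train_ids else setdiff(ids, test_ids)
  if (length(intersect(train_ids, test_ids))) {
    stop("train and test participant sets overlap: ",
         paste(intersect(train_ids, test_ids), collapse = ", "))
  }
  seeds <- derive_seeds(ec$seed, n + 3L)
  conds <- protocol_conditions(config)
  nb <- nrow(conds)

  train_windows <- list(); train_info <- list()
  train_shapes <- list(); train_stride_info <- list()
  feat_rows <- list()
  test_bouts <- list()
  recovery <- list()

  for (i in seq_len(n)) {
    id <- ids[i]
    p <- synthetic_participant(id, seeds[i], config)
    bseeds <- derive_seeds(seeds[i], 3L * nb)
    for (b in seq_len(nb)) {
      cond <- conds[b, ]
      bout <- simulate_bout(p, cond$activity, cond$intensity, cond$incline_pct,
                            cond$duration_s, seed = bseeds[b], config = config)
      breaths <- simulate_breaths(
        bout$true_ee * p$mass_kg,
        condition_rer(p, cond$activity, cond$intensity),
        cond$duration_s, noise_cv = config$synth$breath_noise_cv,
        seed = bseeds[nb + b], config = config)
      pr <- process_bout(bout, breaths, config)
      ne <- length(pr$epochs)

      if (bout$activity %in% c("walking", "running", "cycling")) {
        recovery[[length(recovery) + 1]] <- data.frame(
          participant = id, activity = bout$activity,
          intensity = bout$intensity, incline_pct = bout$incline_pct,
          true_strides = bout$true_stride_count,
          detected_strides = pr$n_detected_strides,
          true_freq_hz = bout$stride_freq_hz, cadence_hz = pr$cadence)
      }
      feat <- data.frame(
        participant = id, bout = b, activity = bout$activity,
        enmo = pr$epochs$info$enmo, mad = pr$epochs$info$mad,
        ee = pr$ref_ee, true_ee = bout$true_ee)

      if (id %in% train_ids) {
        sub <- with_seed(bseeds[2L * nb + b],
                         sort(sample.int(ne, min(ec$windows_per_bout_train, ne))))
        train_windows[[length(train_windows) + 1]] <-
          pr$epochs$windows[sub, , , drop = FALSE]
        train_info[[length(train_info) + 1]] <- data.frame(
          true_label = pr$epochs$info$true_label[sub], participant = id)
        if (!is.null(pr$strides) && nrow(pr$strides$info)) {
          ns <- nrow(pr$strides$info)
          ssub <- with_seed(bseeds[2L * nb + b] + 1L,
                            sort(sample.int(ns, min(ec$strides_per_bout_train, ns))))
          train_shapes[[length(train_shapes) + 1]] <-
            pr$strides$shapes[ssub, , , drop = FALSE]
          train_stride_info[[length(train_stride_info) + 1]] <- data.frame(
            activity = rep(bout$activity, length(ssub)),
            ref_ee = pr$ref_ee, participant = id)
        }
        feat_rows[[length(feat_rows) + 1]] <- feat
      } else {
        test_bouts[[length(test_bouts) + 1]] <- list(
          participant = id, bout = b, activity = bout$activity,
          intensity = bout$intensity, incline_pct = bout$incline_pct,
          epochs = pr$epochs, ref_ee = pr$ref_ee, feat = feat)
      }
    }
    log_("simulated %s (%s)", id, if (id %in% test_ids) "test" else "train")
  }

  # ---- training ----
  tr_epochs <- epoch_set(
    do.call(abind3, train_windows),
    within(do.call(rbind, train_info), {
      index <- seq_along(true_label) - 1L
      start_time <- 0
      predicted_label <- NA_character_
    })
  )
  classifier <- build_classifier(config, seed = seeds[n + 1L])
  classifier <- train_classifier(classifier, tr_epochs, config,
                                 seed = seeds[n + 1L])
  log_("classifier trained: best val loss %.4f", classifier$val_loss)

  feats <- do.call(rbind, feat_rows)
  lin <- list(
    enmo = fit_linear_ee(feats, "enmo", FALSE),
    mad = fit_linear_ee(feats, "mad", FALSE),
    enmo_activity = fit_linear_ee(feats, "enmo", TRUE),
    mad_activity = fit_linear_ee(feats, "mad", TRUE)
  )
  tr_strides <- stride_set(
    do.call(rbind, train_stride_info),
    do.call(abind3, train_shapes)
  )
  tcn <- build_tcn_ee(config, seed = seeds[n + 2L])
  tcn <- train_tcn_ee(tcn, tr_strides, config, seed = seeds[n + 2L])
  log_("stride EE model trained: best val loss %.4f", tcn$val_loss)

  # ---- evaluation on the test split ----
  pred_rows <- list()
  for (tb in test_bouts) {
    ep <- predict_activities(classifier, tb$epochs)
    seqs <- group_sequences(ep, config = config)
    acc <- windows_to_acc(ep)
    strides <- segment_sequences(acc, seqs, config$sample_rate_hz, config)
    ts <- compose_catse3(ep, strides, tcn, lin$enmo_activity, config)
    pl <- ep$info$predicted_label
    pred_rows[[length(pred_rows) + 1]] <- data.frame(
      participant = tb$participant, bout = tb$bout,
      activity = tb$activity, intensity = tb$intensity,
      incline_pct = tb$incline_pct,
      true_label = ep$info$true_label, predicted_label = pl,
      ref_ee = tb$ref_ee, true_ee = tb$feat$true_ee,
      catse3 = ts$ee_kcal_kg_min, source = ts$source,
      enmo = predict_linear_ee(lin$enmo, ep$info$enmo),
      mad = predict_linear_ee(lin$mad, ep$info$mad),
      enmo_activity = predict_linear_ee(lin$enmo_activity, ep$info$enmo, pl),
      mad_activity = predict_linear_ee(lin$mad_activity, ep$info$mad, pl))
  }
  pred <- do.call(rbind, pred_rows)
  cls_report <- classification_report(pred$true_label, pred$predicted_label)
  model_cols <- c(CATSE3 = "catse3", ENMO = "enmo", MAD = "mad",
                  `ENMO + activity` = "enmo_activity",
                  `MAD + activity` = "mad_activity")
  ee_reports <- lapply(model_cols, function(cl) {
    regression_report(pred[[cl]], pred$ref_ee)
  })
  log_("test accuracy %.4f; CATSE3 MAPE %.1f%%", cls_report$accuracy,
       ee_reports$CATSE3$mape)

  structure(list(
    config = config,
    train_ids = train_ids, test_ids = test_ids,
    classifier = classifier, tcn = tcn, linear_models = lin,
    classification = cls_report,
    ee_reports = ee_reports,
    comparison = comparison_table(ee_reports),
    stride_recovery = do.call(rbind, recovery),
    predictions = pred
  ), class = "catse3_experiment")
}

# reconstruct the contiguous acceleration matrix underlying an epoch set
windows_to_acc <- function(epochs) {
  d <- dim(epochs$windows)
  acc <- matrix(NA_real_, d[1] * d[2], 3)
  for (e in seq_len(d[1])) {
    acc[((e - 1) * d[2] + 1):(e * d[2]), ] <- epochs$windows[e, , ]
  }
  acc
}

#' @export
print.catse3_experiment <- function(x, ...) {
  cat(sprintf("<catse3 experiment> %d train / %d test participants\n",
              length(x$train_ids), length(x$test_ids)))
  cat(sprintf("classification accuracy: %.4f (n = %d epochs)\n",
              x$classification$accuracy, x$classification$n))
  cat("energy-expenditure model comparison:\n")
  print(transform(x$comparison,
                  bias = round(bias, 4), loa_lower = round(loa_lower, 4),
                  loa_upper = round(loa_upper, 4), rmse = round(rmse, 4),
                  mape = round(mape, 1), r2 = round(r2, 3)),
        row.names = FALSE)
  invisible(x)
}
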