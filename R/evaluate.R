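#' Classification performance report
#'
#' Confusion matrix (rows = truth) over the five-class vocabulary plus
#' overall accuracy and per-class recall, precision and F1:
#' accuracy = true positives / n; recall = TP / (TP + FN);
#' precision = TP / (TP + FP); F1 = harmonic mean of recall and precision.
#' Classes absent from both truth and prediction get `NA` metrics with an
#' `undefined` flag rather than 0.
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels, same length.
#' @param levels Label vocabulary (default [activity_levels()]).
#' @return An object of class `"classification_report"` with elements
#'   `confusion` (5x5 counts), `accuracy`, `per_class` (data frame with
#'   recall/precision/f1/undefined), `n`.
#' @export
classification_report <- function(truth, predicted, levels = activity_levels()) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  tf <- factor(truth, levels = levels)
  pf <- factor(predicted, levels = levels)
  cm <- table(truth = tf, predicted = pf)
  n <- length(truth)
  acc <- sum(diag(cm)) / n
  per <- data.frame(class = levels, recall = NA_real_, precision = NA_real_,
                    f1 = NA_real_, undefined = FALSE)
  for (i in seq_along(levels)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    if (tp + fn + fp == 0) {
      per$undefined[i] <- TRUE
      next
    }
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per$recall[i] <- r
    per$precision[i] <- p
    per$f1[i] <- if (!is.na(r) && !is.na(p) && (r + p) > 0) 2 * p * r / (p + r) else NA_real_
  }
  structure(list(confusion = cm, accuracy = acc, per_class = per, n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification report> n = %d, accuracy = %.4f\n", x$n, x$accuracy))
  print(x$confusion)
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Regression performance report
#'
#' The method-validation metric suite for energy-expenditure estimates:
#' RMSE = sqrt(mean((p - r)^2)); MAPE = 100 * mean(|p - r| / r);
#' R2 = 1 - SSres/SStot (not clipped, can be negative);
#' bias = mean(p - r); 95% limits of agreement = bias +/- 1.96 * SD(p - r)
#' (conventional Bland-Altman form with sample SD). MAPE is marked
#' undefined when any reference is non-positive; the other metrics are
#' still computed.
#'
#' @param predicted Numeric vector of predictions.
#' @param reference Numeric vector of reference values, same length.
#' @return An object of class `"regression_report"` with `rmse`, `mape`
#'   (percent, possibly `NA`), `mape_undefined`, `r2`, `bias`,
#'   `loa_lower`, `loa_upper`, `n`.
#' @export
regression_report <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must have equal length")
  }
  stopifnot(all(is.finite(predicted)), all(is.finite(reference)))
  d <- predicted - reference
  rmse <- sqrt(mean(d^2))
  mape_undef <- any(reference <= 0)
  mape <- if (mape_undef) NA_real_ else 100 * mean(abs(d) / reference)
  sstot <- sum((reference - mean(reference))^2)
  r2 <- 1 - sum(d^2) / sstot
  bias <- mean(d)
  sdd <- stats::sd(d)
  if (length(d) == 1 || !is.finite(sdd)) sdd <- 0
  structure(list(
    rmse = rmse, mape = mape, mape_undefined = mape_undef, r2 = r2,
    bias = bias, loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
    n = length(d)
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression report> n = %d\n  bias %.4f  LoA [%.4f, %.4f]  RMSE %.4f  MAPE %s  R2 %.4f\n",
    x$n, x$bias, x$loa_lower, x$loa_upper, x$rmse,
    if (is.na(x$mape)) "undefined" else sprintf("%.1f%%", x$mape), x$r2
  ))
  invisible(x)
}

#' Sample Pearson correlation
#'
#' Standard sample Pearson correlation coefficient; returns `NA` with a
#' warning when either vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  sum(dx * dy) / sqrt(vx * vy)
}

#' Render a model-comparison table
#'
#' Text table of regression reports in the conventional column order
#' (bias, limits of agreement, RMSE, MAPE, R2).
#'
#' @param reports Named list of `regression_report` objects.
#' @return A data frame (one row per model), printed-friendly.
#' @export
comparison_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, bias = r$bias, loa_lower = r$loa_lower,
               loa_upper = r$loa_upper, rmse = r$rmse, mape = r$mape,
               r2 = r$r2, n = r$n)
  }))
}
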