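#' Mean absolute error
#'
#' `MAE = (1/n) * sum(|y_i - yhat_i|)`, in the units of the inputs (degrees
#' for amplitude series).
#'
#' @param y ground-truth vector.
#' @param yhat predicted vector, same length.
#' @return non-negative scalar.
#' @export
mae <- function(y, yhat) {
  check_pair(y, yhat)
  mean(abs(y - yhat))
}

#' Mean absolute percentage error with a near-zero exclusion threshold
#'
#' `MAPE = (1/n) * sum(|(y_i - yhat_i) / y_i|) * 100`, computed after
#' dropping pairs whose ground-truth magnitude is below `threshold` (dividing
#' by near-zero ground truth produces unbounded percentage errors; the
#' standard setting excludes absolute angles between 0 and 1 degree).
#'
#' @inheritParams mae
#' @param threshold exclusion threshold on `|y|` (default 1, degrees).
#' @return list with `mape` (percent) and `n_excluded`.
#' @export
mape <- function(y, yhat, threshold = 1) {
  check_pair(y, yhat)
  keep <- abs(y) >= threshold
  if (!any(keep)) {
    stop_romval("MAPE undefined: all pairs excluded by the threshold",
                "romval_metric_error")
  }
  list(mape = mean(abs((y[keep] - yhat[keep]) / y[keep])) * 100,
       n_excluded = sum(!keep))
}

#' Pearson correlation with a two-sided p-value
#'
#' @inheritParams mae
#' @return list with `r` and `p_value`.
#' @export
pearson_r <- function(y, yhat) {
  check_pair(y, yhat)
  if (length(y) < 3L) {
    stop_romval("Pearson correlation needs n >= 3", "romval_metric_error")
  }
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop_romval("Pearson correlation undefined for zero-variance input",
                "romval_metric_error")
  }
  ct <- stats::cor.test(y, yhat, alternative = "two.sided", method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Cosine similarity of two raw (non-centered) vectors
#'
#' `(y . yhat) / (|y| |yhat|)`. Unlike the Pearson coefficient the vectors
#' are not centered, so the measure is insensitive to a positive rescaling of
#' either input and captures the morphology of the signals regardless of
#' magnitude.
#'
#' @inheritParams mae
#' @return scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(y, yhat) {
  check_pair(y, yhat)
  ny <- sqrt(sum(y^2)); nh <- sqrt(sum(yhat^2))
  if (ny == 0 || nh == 0) {
    stop_romval("cosine similarity undefined for a zero vector", "romval_metric_error")
  }
  sum(y * yhat) / (ny * nh)
}

#' Ordinary least squares fit mapping predictions to ground truth
#'
#' Fits `y = slope * x + intercept` with `x` the predicted amplitudes and `y`
#' the ground-truth amplitudes (the direction that maps model output into
#' expected values), and reports `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param x predicted amplitudes (degrees).
#' @param y ground-truth amplitudes (degrees).
#' @return object of class `regression_result`: `slope`, `intercept`
#'   (degrees), `r_squared`.
#' @export
linear_fit <- function(x, y) {
  check_pair(y, x)
  if (length(x) < 3L) {
    stop_romval("regression needs n >= 3", "romval_metric_error")
  }
  if (stats::var(x) == 0) {
    stop_romval("regression undefined: predictor has zero variance",
                "romval_metric_error")
  }
  fit <- stats::lm.fit(cbind(intercept = 1, slope = x), y)
  res <- fit$residuals
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  structure(
    list(slope = unname(fit$coefficients["slope"]),
         intercept = unname(fit$coefficients["intercept"]),
         r_squared = min(1, max(0, r2))),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4f x + %.4f (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

check_pair <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop_romval("vectors must have equal length", "romval_validation_error")
  }
  if (!length(y)) {
    stop_romval("vectors must be non-empty", "romval_validation_error")
  }
  if (anyNA(y) || anyNA(yhat)) {
    stop_romval("vectors must not contain missing values", "romval_validation_error")
  }
  invisible(TRUE)
}

#' Per-repetition peak amplitudes of an aligned pair
#'
#' For every repetition window, the maximum ground-truth value and the
#' maximum predicted value among the aligned samples inside the window, as
#' paired vectors. Windows containing no samples are skipped with a warning.
#'
#' @param aligned an `aligned_pair`.
#' @param reps list of `repetition_window`s (see [segment_repetitions()]).
#' @return list with vectors `gt` and `pred` (one entry per non-empty
#'   window).
#' @export
peak_amplitudes <- function(aligned, reps) {
  if (!length(reps)) {
    stop_romval("no repetition windows", "romval_validation_error")
  }
  gt <- pred <- numeric(0)
  for (w in reps) {
    sel <- aligned$times >= w$start_s & aligned$times <= w$end_s
    if (!any(sel)) {
      warning("repetition window [", w$start_s, ", ", w$end_s,
              "] contains no aligned samples; skipped")
      next
    }
    gt <- c(gt, max(aligned$gt_values[sel]))
    pred <- c(pred, max(aligned$pred_values[sel]))
  }
  list(gt = gt, pred = pred)
}

# Aligned samples falling inside any repetition window.
motion_samples <- function(aligned, reps) {
  sel <- rep(FALSE, length(aligned$times))
  for (w in reps) {
    sel <- sel | (aligned$times >= w$start_s & aligned$times <= w$end_s)
  }
  list(gt = aligned$gt_values[sel], pred = aligned$pred_values[sel])
}

#' Evaluate agreement between ground truth and prediction for one exercise
#'
#' Computes the full metric battery from an aligned pair and its repetition
#' windows, from two perspectives: peak amplitudes (one maximum per
#' repetition — static-pose accuracy) and motion amplitudes (every aligned
#' sample inside a repetition window — dynamic accuracy). The MAPE near-zero
#' exclusion threshold applies to both blocks (it only ever excludes motion
#' samples in practice, peaks being far from zero); the regression mapping
#' predicted to ground-truth amplitudes is computed on motion amplitudes.
#'
#' @param aligned an `aligned_pair`.
#' @param reps list of `repetition_window`s.
#' @param threshold MAPE exclusion threshold in degrees (default 1).
#' @param exercise exercise code stored in the report.
#' @return object of class `evaluation_report` with blocks `peak` (mae_deg,
#'   mape_pct, pearson_r, p_value, cosine_sim, n) and `motion` (the same plus
#'   `regression` and `n_excluded_by_threshold`).
#' @export
evaluate_exercise <- function(aligned, reps, threshold = 1,
                              exercise = NA_character_) {
  pk <- peak_amplitudes(aligned, reps)
  mo <- motion_samples(aligned, reps)
  pk_mape <- mape(pk$gt, pk$pred, threshold)
  pk_cor <- pearson_r(pk$gt, pk$pred)
  # the near-zero threshold defines the motion-amplitude dataset: every
  # motion metric is computed on the surviving pairs
  mo_keep <- abs(mo$gt) >= threshold
  if (!any(mo_keep)) {
    stop_romval("no motion samples survive the threshold filter", "romval_metric_error")
  }
  mo_mape <- mape(mo$gt, mo$pred, threshold)
  mo_cor <- pearson_r(mo$gt[mo_keep], mo$pred[mo_keep])
  structure(
    list(
      exercise = exercise,
      mape_threshold_deg = threshold,
      peak = list(
        mae_deg = mae(pk$gt, pk$pred),
        mape_pct = pk_mape$mape,
        pearson_r = pk_cor$r, p_value = pk_cor$p_value,
        cosine_sim = cosine_similarity(pk$gt, pk$pred),
        n = length(pk$gt)
      ),
      motion = list(
        mae_deg = mae(mo$gt[mo_keep], mo$pred[mo_keep]),
        mape_pct = mo_mape$mape,
        pearson_r = mo_cor$r, p_value = mo_cor$p_value,
        cosine_sim = cosine_similarity(mo$gt[mo_keep], mo$pred[mo_keep]),
        regression = linear_fit(mo$pred[mo_keep], mo$gt[mo_keep]),
        n = sum(mo_keep),
        n_excluded_by_threshold = mo_mape$n_excluded
      )
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$exercise, "\n")
  cat(sprintf("  peak   : MAE %6.2f deg  MAPE %6.2f%%  r %.3f  cos %.3f  (n=%d)\n",
              x$peak$mae_deg, x$peak$mape_pct, x$peak$pearson_r,
              x$peak$cosine_sim, x$peak$n))
  cat(sprintf("  motion : MAE %6.2f deg  MAPE %6.2f%%  r %.3f  cos %.3f  (n=%d, excl=%d)\n",
              x$motion$mae_deg, x$motion$mape_pct, x$motion$pearson_r,
              x$motion$cosine_sim, x$motion$n, x$motion$n_excluded_by_threshold))
  cat(sprintf("  motion regression: y = %.3f x + %.3f (R^2 %.3f)\n",
              x$motion$regression$slope, x$motion$regression$intercept,
              x$motion$regression$r_squared))
  invisible(x)
}

#' Flatten an evaluation report to a one-row data frame
#'
#' Column layout mirrors the summary tables of a validation study: one row
#' per exercise with peak and motion metric blocks side by side.
#'
#' @param report an `evaluation_report`.
#' @return a one-row `data.frame`.
#' @export
report_as_row <- function(report) {
  data.frame(
    exercise = report$exercise,
    peak_mae_deg = report$peak$mae_deg,
    peak_mape_pct = report$peak$mape_pct,
    peak_pearson_r = report$peak$pearson_r,
    peak_cosine_sim = report$peak$cosine_sim,
    peak_n = report$peak$n,
    motion_mae_deg = report$motion$mae_deg,
    motion_mape_pct = report$motion$mape_pct,
    motion_pearson_r = report$motion$pearson_r,
    motion_cosine_sim = report$motion$cosine_sim,
    motion_slope = report$motion$regression$slope,
    motion_intercept_deg = report$motion$regression$intercept,
    motion_r_squared = report$motion$regression$r_squared,
    motion_n = report$motion$n,
    motion_n_excluded = report$motion$n_excluded_by_threshold,
    stringsAsFactors = FALSE
  )
}
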