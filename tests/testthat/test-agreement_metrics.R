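test_that("mae matches hand evaluation", {
  expect_equal(mae(c(0, 0), c(1, -1)), 1.0)
  expect_equal(mae(c(10, 20, 30), c(10, 20, 30)), 0.0)
  expect_equal(mae(c(10, 20, 30), c(12, 17, 30)), 5 / 3)
  expect_error(mae(1:3, 1:4), class = "romval_validation_error")
})

test_that("mape applies the near-zero exclusion threshold", {
  expect_equal(mape(100, 90)$mape, 10.0)
  expect_equal(mape(c(2, 4), c(1, 5))$mape, 37.5)
  r <- mape(c(0.5, 100), c(99, 100))
  expect_equal(r$mape, 0.0)
  expect_equal(r$n_excluded, 1L)
  expect_error(mape(c(0.1, 0.2), c(1, 1)), class = "romval_metric_error")
})

test_that("pearson and cosine behave at their fixed points", {
  y <- c(3, 7, 1, 9, 4)
  expect_equal(pearson_r(y, 2 * y + 3)$r, 1.0, tolerance = 1e-12)
  expect_equal(pearson_r(y, -y)$r, -1.0, tolerance = 1e-12)
  expect_error(pearson_r(y, rep(5, 5)), class = "romval_metric_error")
  expect_error(pearson_r(c(1, 2), c(3, 4)), class = "romval_metric_error")
  expect_equal(cosine_similarity(y, 0.5 * y), 1.0, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), class = "romval_metric_error")
})

test_that("linear_fit recovers exact lines and validates input", {
  x <- c(10, 35, 60, 85, 110)
  f1 <- linear_fit(x, x)
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-10)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  f2 <- linear_fit(x, 0.89 * x + 1.72)
  expect_equal(f2$slope, 0.89, tolerance = 1e-12)
  expect_equal(f2$intercept, 1.72, tolerance = 1e-10)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)
  expect_error(linear_fit(rep(2, 5), x), class = "romval_metric_error")
})

test_that("all metrics match brute-force oracles on randomized vectors", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    y <- stats::runif(n, 0, 120)
    yhat <- y + stats::rnorm(n, 0, 10)
    expect_equal(mae(y, yhat), oracle_mae(y, yhat), tolerance = 1e-10)
    if (any(abs(y) >= 1)) {
      m <- mape(y, yhat, 1); o <- oracle_mape(y, yhat, 1)
      expect_equal(m$mape, o$mape, tolerance = 1e-10)
      expect_identical(m$n_excluded, o$n_excluded)
    }
    if (stats::sd(y) > 0 && stats::sd(yhat) > 0) {
      expect_equal(pearson_r(y, yhat)$r, oracle_pearson(y, yhat), tolerance = 1e-10)
    }
    expect_equal(cosine_similarity(y, yhat), oracle_cosine(y, yhat),
                 tolerance = 1e-10)
    f <- linear_fit(yhat, y); o <- oracle_ols(yhat, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-8)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-8)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
  }
})

test_that("mape and cosine are invariant to positive rescaling", {
  set.seed(17)
  y <- stats::runif(40, 2, 150); yhat <- y + stats::rnorm(40, 0, 5)
  for (c in c(0.5, 3, 42)) {
    expect_equal(mape(c * y, c * yhat, threshold = c)$mape,
                 mape(y, yhat, threshold = 1)$mape, tolerance = 1e-10)
    expect_equal(cosine_similarity(y, c * yhat), cosine_similarity(y, yhat),
                 tolerance = 1e-12)
  }
})

make_aligned <- function(times, gt, pred) {
  structure(list(times = times, gt_values = gt, pred_values = pred,
                 offset_s = 0, match_tolerance_s = 1 / 600,
                 dt_s = rep(0, length(times))), class = "aligned_pair")
}

test_that("peak_amplitudes extracts per-window maxima", {
  t <- seq(0, 10, by = 0.1)
  gt <- ifelse(t < 5, 45 * (1 - cos(2 * pi * t / 5)), 30 * (1 - cos(2 * pi * (t - 5) / 5)))
  ap <- make_aligned(t, gt, gt)
  reps <- list(
    structure(list(start_s = 0, end_s = 5, peak_time_s = 2.5,
                   peak_amplitude_deg = 90), class = "repetition_window"),
    structure(list(start_s = 5, end_s = 10, peak_time_s = 7.5,
                   peak_amplitude_deg = 60), class = "repetition_window")
  )
  pk <- peak_amplitudes(ap, reps)
  expect_equal(pk$gt, c(90, 60), tolerance = 1e-9)
  expect_identical(pk$gt, pk$pred)
  # a window with no samples is skipped with a warning
  reps3 <- c(reps, list(structure(list(start_s = 50, end_s = 51, peak_time_s = 50.5,
                                       peak_amplitude_deg = 1),
                                  class = "repetition_window")))
  expect_warning(pk3 <- peak_amplitudes(ap, reps3), "no aligned samples")
  expect_length(pk3$gt, 2L)
})

test_that("evaluate_exercise hits the perfect-agreement fixed point", {
  t <- seq(0, 42, by = 0.1)
  prof <- angle_profile(protocol_spec(), seed = 31)
  gt <- prof$fn(t)
  ap <- make_aligned(t, gt, gt)
  pk <- detect_peaks(amplitude_series(t, gt))
  reps <- segment_repetitions(ap, pk)
  rep_ <- evaluate_exercise(ap, reps, threshold = 1, exercise = "SA")
  expect_equal(rep_$peak$mae_deg, 0)
  expect_equal(rep_$motion$mae_deg, 0)
  expect_equal(rep_$peak$mape_pct, 0)
  expect_equal(rep_$motion$mape_pct, 0)
  expect_equal(rep_$peak$pearson_r, 1, tolerance = 1e-12)
  expect_equal(rep_$motion$pearson_r, 1, tolerance = 1e-12)
  expect_equal(rep_$motion$cosine_sim, 1, tolerance = 1e-12)
  expect_equal(rep_$motion$regression$slope, 1, tolerance = 1e-9)
  expect_equal(rep_$motion$regression$intercept, 0, tolerance = 1e-9)
  expect_equal(rep_$motion$regression$r_squared, 1, tolerance = 1e-12)
  expect_gt(rep_$motion$n, 0L)
  expect_lt(rep_$peak$p_value, 1e-6)
  # report invariants
  expect_gte(rep_$motion$mae_deg, 0)
  expect_lte(abs(rep_$motion$pearson_r), 1)
  expect_true(rep_$motion$regression$r_squared >= 0 &&
                rep_$motion$regression$r_squared <= 1)
})

test_that("motion n counts only threshold survivors", {
  # three windows, each with 20 sub-threshold and 40 supra-threshold samples
  t <- seq(0, 17.9, by = 0.1)
  block <- function(top) c(rep(0.5, 20), seq(2, top, length.out = 40))
  gt <- c(block(80), block(70), block(90))
  ap <- make_aligned(t, gt, gt + 1)
  reps <- lapply(0:2, function(k) {
    structure(list(start_s = 6 * k, end_s = 6 * k + 5.9,
                   peak_time_s = 6 * k + 5.9, peak_amplitude_deg = max(gt)),
              class = "repetition_window")
  })
  rep_ <- evaluate_exercise(ap, reps, threshold = 1)
  expect_equal(rep_$motion$n, 120L)
  expect_equal(rep_$motion$n_excluded_by_threshold, 60L)
})
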