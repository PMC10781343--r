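# raised-cosine pulse train sampled at a given rate, as an amplitude series
pulse_series <- function(fps, peak_times, amps, duration, rep_period = 3,
                         source = "ground_truth") {
  t <- seq(0, duration, by = 1 / fps)
  v <- numeric(length(t))
  for (k in seq_along(peak_times)) {
    inside <- abs(t - peak_times[k]) <= rep_period / 2
    v[inside] <- amps[k] / 2 * (1 + cos(2 * pi * (t[inside] - peak_times[k]) / rep_period))
  }
  amplitude_series(t, v, source = source, fps = fps)
}

test_that("frames_to_seconds converts at both acquisition rates", {
  expect_equal(frames_to_seconds(100, 100), 1.0)
  expect_equal(frames_to_seconds(30, 30), 1.0)
  expect_equal(frames_to_seconds(0, 77), 0.0)
  expect_error(frames_to_seconds(-1, 30), class = "romval_validation_error")
  expect_error(frames_to_seconds(1, 0), class = "romval_validation_error")
})

test_that("detect_peaks finds pulse apexes and ignores flat series", {
  tri <- amplitude_series(seq(0, 2, by = 0.1),
                          c(seq(0, 90, length.out = 10), seq(81, 0, length.out = 11)),
                          fps = 10)
  pk <- detect_peaks(tri)
  expect_length(pk$times, 1L)
  expect_equal(pk$amplitudes, 90)

  flat <- amplitude_series(seq(0, 2, by = 0.1), rep(5, 21), fps = 10)
  expect_length(detect_peaks(flat)$times, 0L)

  prof <- angle_profile(protocol_spec(per_rep_jitter_deg = 0), seed = 1)
  s <- pulse_series(30, prof$peak_times, prof$peak_amps, prof$duration)
  pk7 <- detect_peaks(s)
  expect_length(pk7$times, 14L)
  expect_true(all(abs(pk7$times - prof$peak_times) <= 1 / 30 + 1e-9))

  expect_error(detect_peaks(amplitude_series(c(0, 1, 2), rep(NA_real_, 3))),
               class = "romval_data_error")
})

test_that("missing samples break peak neighborhoods", {
  # two pulses separated by a gap of missing data: both found independently
  t <- seq(0, 6, by = 0.1)
  v <- ifelse(abs(t - 1) <= 1, 45 * (1 + cos(pi * (t - 1))), 0)
  v[t > 2 & t < 4] <- NA
  v <- ifelse(!is.na(v) & abs(t - 5) <= 1, 45 * (1 + cos(pi * (t - 5))), v)
  pk <- detect_peaks(amplitude_series(t, v, fps = 10))
  expect_length(pk$times, 2L)
})

test_that("coarse alignment is the first-peak time difference", {
  gt <- structure(list(times = c(3.2, 6.2), amplitudes = c(90, 88),
                       indices = c(1L, 2L)), class = "peak_set")
  pred <- structure(list(times = c(1.2, 4.2), amplitudes = c(89, 87),
                         indices = c(1L, 2L)), class = "peak_set")
  expect_equal(coarse_align_first_peak(gt, pred), 2.0)
  expect_equal(coarse_align_first_peak(gt, gt), 0.0)
  empty <- structure(list(times = numeric(0), amplitudes = numeric(0),
                          indices = integer(0)), class = "peak_set")
  expect_error(coarse_align_first_peak(gt, empty), class = "romval_alignment_error")
})

test_that("match_samples pairs the two native rate grids as documented", {
  prof <- angle_profile(protocol_spec(), seed = 2)
  gt <- pulse_series(100, prof$peak_times, prof$peak_amps, prof$duration)
  pred <- pulse_series(30, prof$peak_times, prof$peak_amps, prof$duration,
                       source = "predicted")
  # 5 ms tolerance keeps every predicted sample (gt spacing 10 ms)
  ap5 <- match_samples(gt, pred, 0, tolerance_s = 0.005)
  expect_length(ap5$times, length(pred$times))
  expect_true(all(ap5$dt_s <= 0.005))
  # the default tolerance keeps exactly the simultaneous 10 Hz subset
  ap <- match_samples(gt, pred, 0)
  # grids coincide every 3rd predicted sample (10 Hz common grid)
  expect_equal(length(ap$times), (length(pred$times) - 1L) %/% 3L + 1L)
  expect_true(all(ap$dt_s <= 1e-9))
  expect_equal(ap$gt_values, ap$pred_values, tolerance = 1e-12)
  # equal-rate equal-clock: identity pairing
  api <- match_samples(gt, gt, 0)
  expect_equal(api$gt_values, gt$values)
  expect_length(api$times, length(gt$times))
  # offset beyond the record: nothing matches
  expect_error(match_samples(gt, pred, 1e6), class = "romval_alignment_error")
})

test_that("match_samples snaps the offset onto the ground-truth grid", {
  prof <- angle_profile(protocol_spec(), seed = 2)
  gt <- pulse_series(100, prof$peak_times, prof$peak_amps, prof$duration)
  pred <- pulse_series(30, prof$peak_times, prof$peak_amps, prof$duration)
  ap <- match_samples(gt, pred, 0.0037)
  expect_equal(ap$offset_s, 0.00)
  ap2 <- match_samples(gt, pred, 0.117)
  expect_equal(ap2$offset_s, 0.12)
})

test_that("fine tuning maximizes Pearson r and skips spurious first peaks", {
  prof <- angle_profile(protocol_spec(), seed = 4)
  gt <- pulse_series(100, prof$peak_times, prof$peak_amps, prof$duration)
  pred <- pulse_series(30, prof$peak_times, prof$peak_amps, prof$duration,
                       source = "predicted")
  gp <- detect_peaks(gt); pp <- detect_peaks(pred)
  ap <- fine_tune_alignment(gt, pred, gp, pp)
  expect_equal(ap$offset_s, 0)
  expect_gte(attr(ap, "pearson_r"), 1 - 1e-12)

  # ground truth with a spurious low familiarization peak 4 s before the
  # protocol: coarse alignment is off by ~4 s, fine tuning recovers it
  t2 <- seq(0, prof$duration + 4, by = 1 / 100)
  v2 <- numeric(length(t2))
  v2[abs(t2 - 1.0) <= 0.75] <- 30 * (1 + cos(2 * pi * (t2[abs(t2 - 1.0) <= 0.75] - 1.0) / 1.5)) / 2
  for (k in seq_along(prof$peak_times)) {
    ctr <- prof$peak_times[k] + 4
    inside <- abs(t2 - ctr) <= 1.5
    v2[inside] <- prof$peak_amps[k] * (1 + cos(2 * pi * (t2[inside] - ctr) / 3)) / 2
  }
  gt2 <- amplitude_series(t2, v2, source = "ground_truth", fps = 100)
  gp2 <- detect_peaks(gt2)
  coarse_off <- coarse_align_first_peak(gp2, pp)
  ap2 <- fine_tune_alignment(gt2, pred, gp2, pp)
  expect_equal(ap2$offset_s, 4, tolerance = 0.05)
  expect_false(abs(coarse_off - 4) < 0.5)  # coarse really was fooled
  r_coarse <- stats::cor(match_samples(gt2, pred, coarse_off)$gt_values,
                         match_samples(gt2, pred, coarse_off)$pred_values)
  expect_gte(attr(ap2, "pearson_r"), r_coarse)
})

test_that("alignment recovers generator offsets on rendered pairs", {
  tpl <- body_template()
  for (off in c(0, 1.23, 3.8)) {
    pair <- render_pair(tpl, "SA", protocol_spec(),
                        camera_model(start_offset_s = off), seed = 21)
    res <- process_acquisition(pair)
    expect_lt(abs(res$offset_s - off), 1 / 30)
  }
})

test_that("segment_repetitions extracts the protocol windows", {
  prof <- angle_profile(protocol_spec(), seed = 6)
  gt <- pulse_series(100, prof$peak_times, prof$peak_amps, prof$duration)
  pred <- pulse_series(30, prof$peak_times, prof$peak_amps, prof$duration,
                       source = "predicted")
  ap <- match_samples(gt, pred, 0)
  aligned_gt <- amplitude_series(ap$times, ap$gt_values, source = "ground_truth")
  pk <- detect_peaks(aligned_gt)
  reps <- segment_repetitions(ap, pk)
  expect_length(reps, 14L)
  for (w in reps) {
    expect_lt(w$start_s, w$peak_time_s)
    expect_gt(w$end_s, w$peak_time_s)
  }
  # non-overlap
  starts <- vapply(reps, `[[`, numeric(1), "start_s")
  ends <- vapply(reps, `[[`, numeric(1), "end_s")
  expect_true(all(ends[-length(ends)] <= starts[-1] + 1e-9))

  # a half-amplitude repetition is dropped by the 0.6 median filter
  amps2 <- prof$peak_amps; amps2[5] <- amps2[5] * 0.5
  gt2 <- pulse_series(100, prof$peak_times, amps2, prof$duration)
  ap2 <- match_samples(gt2, pred, 0)
  pk2 <- detect_peaks(amplitude_series(ap2$times, ap2$gt_values))
  expect_length(segment_repetitions(ap2, pk2, min_peak_frac = 0.6), 13L)

  # single pulse -> one window spanning it
  one <- pulse_series(30, 2, 90, 4)
  apo <- match_samples(one, one, 0)
  pko <- detect_peaks(amplitude_series(apo$times, apo$gt_values))
  wins <- segment_repetitions(apo, pko)
  expect_length(wins, 1L)
  expect_lte(wins[[1]]$start_s, 0.6)
  expect_gte(wins[[1]]$end_s, 3.4)
})

test_that("fine-tuned r is never below coarse r on randomized noisy pairs", {
  tpl <- body_template()
  for (s in 1:5) {
    set.seed(s + 900)
    off <- stats::runif(1, 0, 5)
    pair <- render_pair(tpl, "MCH", protocol_spec(),
                        camera_model(start_offset_s = off, angle_noise_sd_deg = 1.5),
                        seed = s + 40)
    res <- process_acquisition(pair)
    r_fine <- stats::cor(res$aligned$gt_values, res$aligned$pred_values)
    gp <- detect_peaks(res$gt_series); pp <- detect_peaks(res$pred_series)
    co <- match_samples(res$gt_series, res$pred_series,
                        coarse_align_first_peak(gp, pp))
    r_coarse <- stats::cor(co$gt_values, co$pred_values)
    expect_gte(r_fine, r_coarse - 1e-12)
    expect_true(all(res$aligned$dt_s <= res$aligned$match_tolerance_s))
  }
})
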