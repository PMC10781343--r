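#' Convert a frame index to seconds
#'
#' @param frame_index zero-based frame index (>= 0).
#' @param fps frame rate (Hz, > 0).
#' @return time in seconds, `frame_index / fps`.
#' @export
frames_to_seconds <- function(frame_index, fps) {
  if (!is.numeric(fps) || any(fps <= 0)) {
    stop_romval("fps must be positive", "romval_validation_error")
  }
  if (!is.numeric(frame_index) || any(frame_index < 0)) {
    stop_romval("frame_index must be non-negative", "romval_validation_error")
  }
  frame_index / fps
}

#' Detect repetition peaks in an amplitude series
#'
#' Local maxima filtered by prominence and minimum separation. Prominence of
#' a candidate peak is its height minus the higher of the two lowest valleys
#' separating it from the nearest higher samples on each side (the standard
#' topographic definition). Candidates must have prominence at least
#' `min_prominence_frac * (max - min)` of the series and are kept greedily by
#' decreasing height under the separation constraint. Missing samples break
#' the series into independent segments, so a peak neighborhood never spans
#' a gap.
#'
#' Peak times are optionally refined by a least-squares quadratic fit over a
#' window of `refine_window_s` seconds around the sample maximum (vertex of
#' the parabola, clamped to the window). This makes the estimated peak time
#' continuous and far less sensitive to sample noise than the raw argmax,
#' which matters because stream alignment is driven by peak-time differences.
#' Set `refine_window_s = 0` to use raw sample times. Peak amplitudes are
#' always the raw sample maxima.
#'
#' @param series an [amplitude_series()] with at least 3 non-missing samples.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   series range (default 0.2).
#' @param min_separation_s minimum time between retained peaks in seconds
#'   (default 1.0; repetitions are seconds-scale).
#' @param refine_window_s half-width of the quadratic refinement window in
#'   seconds (default 0.5).
#' @return an object of class `peak_set` with fields `times` (s),
#'   `amplitudes` (deg) and `indices` (1-based sample indices).
#' @export
detect_peaks <- function(series, min_prominence_frac = 0.2,
                         min_separation_s = 1.0, refine_window_s = 0.5) {
  v <- series$values; t <- series$times
  ok <- !is.na(v)
  if (sum(ok) < 3L) {
    stop_romval("peak detection needs at least 3 non-missing samples",
                "romval_data_error")
  }
  rng <- max(v[ok]) - min(v[ok])
  min_prom <- min_prominence_frac * rng
  cand_idx <- integer(0)
  # split into contiguous non-missing runs; find local maxima per run
  runs <- split(which(ok), cumsum(!ok)[ok])
  for (run in runs) {
    if (length(run) < 3L) next
    x <- v[run]
    n <- length(x)
    for (i in 2:(n - 1L)) {
      if (x[i] <= x[i - 1L] || x[i] < x[i + 1L]) next  # strict rise, plateau-left peak
      prom <- peak_prominence(x, i)
      if (prom >= min_prom && prom > 0) cand_idx <- c(cand_idx, run[i])
    }
  }
  if (!length(cand_idx)) {
    return(structure(list(times = numeric(0), amplitudes = numeric(0),
                          indices = integer(0)), class = "peak_set"))
  }
  # greedy separation filter, tallest first
  ordc <- cand_idx[order(-v[cand_idx], t[cand_idx])]
  kept <- integer(0)
  for (i in ordc) {
    if (!length(kept) || all(abs(t[i] - t[kept]) >= min_separation_s)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  times <- t[kept]
  if (refine_window_s > 0) {
    times <- vapply(kept, function(i) {
      refine_peak_time(t, v, i, refine_window_s)
    }, numeric(1L))
    # refinement must keep order; fall back to raw times if it does not
    if (any(diff(times) <= 0)) times <- t[kept]
  }
  structure(list(times = times, amplitudes = v[kept], indices = kept),
            class = "peak_set")
}

# Topographic prominence of x[i] within one contiguous run.
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]; j <- i
  while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; left_min <- min(left_min, x[j]) }
  right_min <- x[i]; j <- i
  while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; right_min <- min(right_min, x[j]) }
  # if the walk reached the run edge without a higher sample, the valley on
  # that side is the run minimum encountered
  x[i] - max(left_min, right_min)
}

# Least-squares parabola over samples within +/- window of t[i]; returns the
# vertex time clamped to the window (raw time if the fit is degenerate).
refine_peak_time <- function(t, v, i, window) {
  sel <- which(!is.na(v) & abs(t - t[i]) <= window)
  if (length(sel) < 3L) return(t[i])
  tt <- t[sel] - t[i]; vv <- v[sel]
  fit <- stats::lm.fit(cbind(1, tt, tt^2), vv)
  a <- fit$coefficients[3L]; b <- fit$coefficients[2L]
  if (!is.finite(a) || a >= 0) return(t[i])
  vertex <- -b / (2 * a)
  t[i] + min(window, max(-window, vertex))
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set>", length(x$times), "peaks\n")
  invisible(x)
}

#' Coarse stream alignment by first-peak time
#'
#' @param gt_peaks,pred_peaks non-empty [detect_peaks()] results for the
#'   ground-truth and predicted amplitude series.
#' @return offset in seconds (`gt first peak time - pred first peak time`);
#'   adding it to predicted sample times co-locates the first peaks.
#' @export
coarse_align_first_peak <- function(gt_peaks, pred_peaks) {
  if (!length(gt_peaks$times) || !length(pred_peaks$times)) {
    stop_romval("cannot align: a peak set is empty", "romval_alignment_error")
  }
  gt_peaks$times[1L] - pred_peaks$times[1L]
}

#' Match samples of two amplitude series under a time offset
#'
#' For each predicted sample time `t`, the ground-truth sample nearest to
#' `t + offset` is selected; the pair is kept iff the residual time
#' difference is at most `tolerance_s` and both values are non-missing.
#' Before matching, the offset is snapped to the ground-truth sample grid
#' (nearest multiple of the ground-truth sample period): when the two streams
#' share a common time grid this makes the retained pairs exactly
#' simultaneous rather than up to half a sample period apart.
#'
#' With the package's native rates (100 and 30 FPS) the grids coincide every
#' tenth of a second, and the default tolerance of 1/600 s retains exactly
#' that 10 Hz simultaneous subset; passing 5 ms instead retains every
#' predicted sample with a nearest-neighbour pairing.
#'
#' @param gt,pred [amplitude_series()] objects.
#' @param offset_s offset in seconds applied to predicted times
#'   (ground-truth clock minus predicted clock).
#' @param tolerance_s maximum residual timestamp difference (default 1/600 s).
#' @return an object of class `aligned_pair` with fields `times` (predicted
#'   clock), `gt_values`, `pred_values`, `offset_s` (snapped),
#'   `match_tolerance_s`, `dt_s` (per-pair residuals).
#' @export
match_samples <- function(gt, pred, offset_s, tolerance_s = 1 / 600) {
  if (!length(gt$times) || !length(pred$times)) {
    stop_romval("cannot match empty series", "romval_alignment_error")
  }
  dt_gt <- if (is.finite(gt$fps) && gt$fps > 0) 1 / gt$fps else
    stats::median(diff(gt$times))
  offset <- round(offset_s / dt_gt) * dt_gt
  target <- pred$times + offset
  idx <- findInterval(target, gt$times, all.inside = FALSE)
  idx0 <- pmax(idx, 1L); idx1 <- pmin(idx + 1L, length(gt$times))
  d0 <- abs(target - gt$times[idx0]); d1 <- abs(target - gt$times[idx1])
  nearest <- ifelse(d1 < d0, idx1, idx0)
  dt <- abs(target - gt$times[nearest])
  keep <- dt <= tolerance_s & !is.na(gt$values[nearest]) & !is.na(pred$values)
  if (!any(keep)) {
    stop_romval("no sample pairs matched within tolerance", "romval_alignment_error")
  }
  structure(
    list(times = pred$times[keep],
         gt_values = gt$values[nearest[keep]],
         pred_values = pred$values[keep],
         offset_s = offset, match_tolerance_s = tolerance_s,
         dt_s = dt[keep]),
    class = "aligned_pair"
  )
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("<aligned_pair>", length(x$times), "matched pairs, offset",
      sprintf("%.4f", x$offset_s), "s\n")
  invisible(x)
}

#' Fine-tune alignment by maximizing Pearson correlation over peak pairs
#'
#' Every pairing of one ground-truth and one predicted peak (restricted to
#' the first `max_peaks` of each stream, keeping the search deterministic and
#' O(`max_peaks`^2)) defines a candidate offset; each candidate is scored by
#' the Pearson correlation of the matched samples and the best-scoring
#' aligned pair is returned. Ties are broken by proximity to the coarse
#' (first-peak) offset. The coarse pairing is itself a candidate, so the
#' fine-tuned correlation is never below the coarse one.
#'
#' @param gt,pred [amplitude_series()] objects.
#' @param gt_peaks,pred_peaks their non-empty peak sets.
#' @param tolerance_s match tolerance, see [match_samples()].
#' @param max_peaks number of leading peaks searched per stream (default 3).
#' @return an `aligned_pair` (with attribute `pearson_r` of the winning
#'   candidate).
#' @export
fine_tune_alignment <- function(gt, pred, gt_peaks, pred_peaks,
                                tolerance_s = 1 / 600, max_peaks = 3L) {
  if (!length(gt_peaks$times) || !length(pred_peaks$times)) {
    stop_romval("cannot align: a peak set is empty", "romval_alignment_error")
  }
  coarse <- coarse_align_first_peak(gt_peaks, pred_peaks)
  gi <- seq_len(min(max_peaks, length(gt_peaks$times)))
  pj <- seq_len(min(max_peaks, length(pred_peaks$times)))
  best <- NULL
  for (i in gi) for (j in pj) {
    off <- gt_peaks$times[i] - pred_peaks$times[j]
    ap <- tryCatch(match_samples(gt, pred, off, tolerance_s),
                   romval_alignment_error = function(e) NULL)
    if (is.null(ap) || length(ap$times) < 2L) next
    if (stats::sd(ap$gt_values) == 0 || stats::sd(ap$pred_values) == 0) next
    r <- stats::cor(ap$gt_values, ap$pred_values)
    if (is.na(r)) next
    better <- is.null(best) || r > best$r + 1e-12 ||
      (abs(r - best$r) <= 1e-12 && abs(off - coarse) < abs(best$off - coarse))
    if (better) best <- list(r = r, off = off, ap = ap)
  }
  if (is.null(best)) {
    stop_romval("no candidate peak pairing yielded >= 2 matched samples",
                "romval_alignment_error")
  }
  attr(best$ap, "pearson_r") <- best$r
  best$ap
}

#' Segment exercise repetitions from an aligned pair
#'
#' One repetition window per retained peak of the aligned ground-truth
#' series: peaks with amplitude below `min_peak_frac` times the median peak
#' amplitude (resting wobble, familiarization, uncompleted trials) are
#' dropped, and each remaining peak is bounded by the nearest local minima of
#' the aligned ground-truth values on each side. Windows are non-overlapping
#' because consecutive peaks share the valley between them.
#'
#' @param aligned an `aligned_pair` (ground-truth values drive segmentation).
#' @param peaks a `peak_set` detected on `aligned$gt_values` (e.g. via
#'   [detect_peaks()] on the aligned ground-truth series).
#' @param min_peak_frac minimum peak amplitude as a fraction of the median
#'   peak amplitude (default 0.6).
#' @return list of `repetition_window` objects with fields `start_s`,
#'   `end_s`, `peak_time_s`, `peak_amplitude_deg`.
#' @export
segment_repetitions <- function(aligned, peaks, min_peak_frac = 0.6) {
  if (!length(peaks$indices)) {
    stop_romval("no peaks to segment", "romval_segmentation_error")
  }
  med <- stats::median(peaks$amplitudes)
  keep <- peaks$amplitudes >= min_peak_frac * med
  if (!any(keep)) {
    stop_romval("no peaks retained by the amplitude filter", "romval_segmentation_error")
  }
  idx <- peaks$indices[keep]
  v <- aligned$gt_values; t <- aligned$times
  n <- length(v)
  windows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    # strict descent: stop at the first sample of a flat valley, so windows
    # separated by a resting plateau do not swallow the whole plateau
    lo <- i
    while (lo > 1L && !is.na(v[lo - 1L]) && v[lo - 1L] < v[lo]) lo <- lo - 1L
    hi <- i
    while (hi < n && !is.na(v[hi + 1L]) && v[hi + 1L] < v[hi]) hi <- hi + 1L
    windows[[k]] <- structure(
      list(start_s = t[max(lo, 1L)], end_s = t[min(hi, n)],
           peak_time_s = t[i], peak_amplitude_deg = v[i]),
      class = "repetition_window"
    )
  }
  windows
}

#' @export
print.repetition_window <- function(x, ...) {
  cat(sprintf("<repetition_window> [%.2f, %.2f] s, peak %.1f deg @ %.2f s\n",
              x$start_s, x$end_s, x$peak_amplitude_deg, x$peak_time_s))
  invisible(x)
}

#' Run the full five-step alignment procedure
#'
#' Steps: (1) both series already carry times in seconds from their frame
#' rates; (2) peaks are detected on each stream; (3) the first-peak offset
#' gives a coarse alignment; (4) ground-truth samples are downsampled onto
#' the predicted time grid by nearest-time matching; (5) the alignment is
#' fine-tuned by choosing the peak pairing that maximizes the Pearson
#' correlation of the matched samples.
#'
#' @param gt,pred [amplitude_series()] objects.
#' @param min_prominence_frac,min_separation_s,refine_window_s peak-detection
#'   settings, see [detect_peaks()].
#' @param tolerance_s match tolerance, see [match_samples()].
#' @param max_peaks fine-tuning search breadth, see [fine_tune_alignment()].
#' @return list with `aligned` (the fine-tuned `aligned_pair`), `coarse`
#'   (the coarse `aligned_pair`), `gt_peaks`, `pred_peaks`, `offset_s`
#'   (fine-tuned, snapped), `coarse_offset_s`.
#' @export
align_streams <- function(gt, pred, min_prominence_frac = 0.2,
                          min_separation_s = 1.0, refine_window_s = 0.5,
                          tolerance_s = 1 / 600, max_peaks = 3L) {
  gt_peaks <- detect_peaks(gt, min_prominence_frac, min_separation_s, refine_window_s)
  pred_peaks <- detect_peaks(pred, min_prominence_frac, min_separation_s, refine_window_s)
  coarse_off <- coarse_align_first_peak(gt_peaks, pred_peaks)
  coarse <- match_samples(gt, pred, coarse_off, tolerance_s)
  fine <- fine_tune_alignment(gt, pred, gt_peaks, pred_peaks, tolerance_s, max_peaks)
  list(aligned = fine, coarse = coarse, gt_peaks = gt_peaks,
       pred_peaks = pred_peaks, offset_s = fine$offset_s,
       coarse_offset_s = coarse$offset_s)
}
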