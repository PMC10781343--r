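#' Project a vector onto a plane
#'
#' Removes the component of `v` along the unit plane normal `n`:
#' `v - (v . n) n`. Restricting the body segment to the plane of movement
#' ensures that only the angle component in that plane is measured.
#'
#' @param v 3-vector.
#' @param n unit 3-vector (plane normal).
#' @return 3-vector orthogonal to `n`.
#' @export
project_onto_plane <- function(v, n) {
  if (!is_finite_vec3(v)) {
    stop_romval("v must be a finite 3-vector", "romval_validation_error")
  }
  if (!is.numeric(n) || length(n) != 3L || abs(vnorm(n) - 1) > 1e-9) {
    stop_romval("n must be a unit 3-vector", "romval_validation_error")
  }
  v - sum(v * n) * n
}

#' Unsigned angle between a projected segment and a reference direction
#'
#' `acos` of the clamped cosine between the two directions, in degrees,
#' in `[0, 180]`. A zero-length input (a segment perpendicular to the plane
#' of movement collapses to zero under projection) yields `NA` rather than
#' an error, since it can legitimately occur frame-by-frame.
#'
#' @param v_proj 3-vector (typically already projected onto the plane of
#'   movement).
#' @param ref 3-vector, the 0-degree reference direction.
#' @return angle in degrees, or `NA` if either vector is (near) zero-length.
#' @export
angle_to_reference <- function(v_proj, ref) {
  if (any(is.nan(c(v_proj, ref)))) {
    stop_romval("NaN input to angle_to_reference", "romval_validation_error")
  }
  nv <- vnorm(v_proj); nr <- vnorm(ref)
  if (nv < 1e-12 || nr < 1e-12) return(NA_real_)
  cosang <- sum(v_proj * ref) / (nv * nr)
  rad2deg(acos(min(1, max(-1, cosang))))
}

# Vectorized worker: rows of V and REF are per-frame vectors; N is the plane
# normal. Returns degrees with NA rows propagated.
angles_projected <- function(V, REF, n) {
  Vp <- V - (V %*% n) %*% t(n)
  Rp <- REF - (REF %*% n) %*% t(n)
  nv <- sqrt(rowSums(Vp^2)); nr <- sqrt(rowSums(Rp^2))
  cosang <- rowSums(Vp * Rp) / (nv * nr)
  out <- rad2deg(acos(pmin(1, pmax(-1, cosang))))
  out[!is.na(nv) & nv < 1e-12] <- NA_real_
  out[!is.na(nr) & nr < 1e-12] <- NA_real_
  out
}

#' Amplitude (ROM) time series container
#'
#' @param times sample times in seconds, strictly increasing.
#' @param values joint amplitudes in degrees, in `[0, 180]`; `NA` marks
#'   frames where the amplitude is undefined (missing landmark or degenerate
#'   projection).
#' @param source `"ground_truth"` or `"predicted"`.
#' @param exercise exercise code.
#' @param fps nominal sampling rate (Hz), used by the alignment stage to
#'   snap offsets onto the sample grid.
#' @return an object of class `amplitude_series`.
#' @export
amplitude_series <- function(times, values, source = "predicted",
                             exercise = NA_character_, fps = NULL) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop_romval("times and values must have equal length", "romval_validation_error")
  }
  if (length(times) && any(diff(times) <= 0)) {
    stop_romval("times must be strictly increasing", "romval_validation_error")
  }
  ok <- !is.na(values)
  if (any(values[ok] < -1e-9 | values[ok] > 180 + 1e-9)) {
    stop_romval("amplitudes must lie in [0, 180] degrees", "romval_validation_error")
  }
  if (is.null(fps)) {
    fps <- if (length(times) > 1L) 1 / stats::median(diff(times)) else NA_real_
  }
  structure(
    list(times = times, values = values, source = source,
         exercise = exercise, fps = fps),
    class = "amplitude_series"
  )
}

#' @export
print.amplitude_series <- function(x, ...) {
  cat("<amplitude_series>", x$exercise, "(", x$source, ")",
      length(x$times), "samples @", round(x$fps, 3), "Hz\n")
  invisible(x)
}

#' Compute the joint-amplitude (ROM) series for one exercise
#'
#' The trajectory must already be expressed in the anatomical convention
#' (+y caudal/down, +z anterior, x sagittal normal): predicted streams via
#' [frame_from_first_visible()] + [transform_to_frame()], ground-truth
#' streams via [apply_axis_convention()]. Per frame, the body segment vector
#' `position(joint2) - position(joint1)` and the reference direction (the
#' constant "down" vector `+y`, or for the squat the per-frame foot->knee
#' vector) are both projected onto the configured plane of movement, and the
#' unsigned angle between them is the amplitude. Frames with a required
#' landmark missing yield `NA`. Sample times are `(frame - 1) / fps`.
#'
#' @param traj a [landmark_trajectory()] in the anatomical convention.
#' @param cfg an `exercise_config` (or exercise code).
#' @param source label stored on the resulting series.
#' @return an [amplitude_series()].
#' @export
compute_amplitude_series <- function(traj, cfg, source = "predicted") {
  if (is.character(cfg)) cfg <- exercise_config(cfg)
  p1 <- joint_positions(traj, cfg$joint1)
  p2 <- joint_positions(traj, cfg$joint2)
  if (traj$n_frames == 1L) { p1 <- matrix(p1, 1L); p2 <- matrix(p2, 1L) }
  seg <- p2 - p1
  if (is.character(cfg$reference) && cfg$reference == "down") {
    REF <- matrix(rep(c(0, 1, 0), each = traj$n_frames), ncol = 3L)
  } else {
    rf <- joint_positions(traj, cfg$reference$from)
    rt <- joint_positions(traj, cfg$reference$to)
    if (traj$n_frames == 1L) { rf <- matrix(rf, 1L); rt <- matrix(rt, 1L) }
    REF <- rt - rf
  }
  vals <- angles_projected(seg, REF, plane_normal_of(cfg))
  amplitude_series(times = (seq_len(traj$n_frames) - 1L) / traj$fps,
                   values = vals, source = source, exercise = cfg$code,
                   fps = traj$fps)
}
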