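# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately use naive loops / textbook formulas so they
# share no code path with the package implementations they check.

oracle_mae <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - yhat[i])
  s / length(y)
}

oracle_mape <- function(y, yhat, threshold = 1) {
  s <- 0; n <- 0L; excl <- 0L
  for (i in seq_along(y)) {
    if (abs(y[i]) < threshold) { excl <- excl + 1L; next }
    s <- s + abs((y[i] - yhat[i]) / y[i])
    n <- n + 1L
  }
  list(mape = 100 * s / n, n_excluded = excl)
}

oracle_pearson <- function(y, yhat) {
  my <- mean(y); mh <- mean(yhat)
  num <- sum((y - my) * (yhat - mh))
  num / sqrt(sum((y - my)^2) * sum((yhat - mh)^2))
}

oracle_cosine <- function(y, yhat) {
  sum(y * yhat) / sqrt(sum(y^2) * sum(yhat^2))
}

oracle_ols <- function(x, y) {
  # normal equations
  sx <- sum(x); sy <- sum(y); n <- length(x)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - slope * x - intercept
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# rotation matrix about an arbitrary unit axis (Rodrigues)
rot_axis_angle <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

random_rotation <- function() {
  rot_axis_angle(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
}

# random valid trajectory for I/O round-trip properties
random_trajectory <- function(n_frames = 8L, skeleton = mocap_skeleton(),
                              fps = 100, na_frac = 0.1) {
  L <- length(skeleton$landmarks)
  pos <- array(stats::rnorm(n_frames * L * 3), dim = c(n_frames, L, 3))
  if (na_frac > 0) {
    drop <- which(stats::runif(n_frames * L) < na_frac)
    for (d in drop) {
      f <- ((d - 1L) %% n_frames) + 1L
      l <- ((d - 1L) %/% n_frames) + 1L
      pos[f, l, ] <- NA_real_
    }
  }
  landmark_trajectory(pos, skeleton, fps)
}

# a 1-frame trajectory from a named landmark position matrix
single_frame_traj <- function(mat, skeleton, fps = 30) {
  landmark_trajectory(array(mat, dim = c(1L, nrow(mat), 3L)), skeleton, fps)
}

# measure the amplitude of one static pose (matrix from pose_from_angle)
measure_pose <- function(mat, skeleton, cfg) {
  compute_amplitude_series(single_frame_traj(mat, skeleton), cfg)$values[1L]
}
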