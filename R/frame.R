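#' RANSAC plane-fit parameters
#'
#' Parameters for the consensus plane fit used when constructing the virtual
#' anatomical frame from the four torso keypoints. With only four points the
#' sampler enumerates all point triples exhaustively (deterministic); random
#' sampling with `random_seed` is used only when the number of triples
#' exceeds `max_trials`.
#'
#' @param residual_threshold inlier distance threshold in meters (> 0).
#' @param min_samples minimal sample size for a candidate plane (>= 3).
#' @param max_trials maximum number of candidate samples.
#' @param random_seed integer seed for the sampler.
#' @return an object of class `plane_fit_params`.
#' @export
plane_fit_params <- function(residual_threshold = 0.01, min_samples = 3L,
                             max_trials = 100L, random_seed = 1L) {
  if (!is.numeric(residual_threshold) || residual_threshold <= 0) {
    stop_romval("residual_threshold must be > 0", "romval_validation_error")
  }
  if (min_samples < 3L) {
    stop_romval("min_samples must be >= 3", "romval_validation_error")
  }
  structure(
    list(residual_threshold = residual_threshold,
         min_samples = as.integer(min_samples),
         max_trials = as.integer(max_trials),
         random_seed = as.integer(random_seed)),
    class = "plane_fit_params"
  )
}

# Total-least-squares plane through a point cloud: the normal is the right
# singular vector of the centered coordinates with the smallest singular
# value. Returns list(normal, rss). Sign is normalized so the largest-
# magnitude component is positive (callers resolve the anatomical sign).
tls_plane <- function(pts) {
  ctr <- colMeans(pts)
  X <- sweep(pts, 2L, ctr)
  sv <- svd(X, nu = 0L, nv = 3L)
  # collinearity: second singular value ~ 0 means no unique plane
  scale <- max(sv$d[1L], .Machine$double.eps)
  if (sv$d[2L] / scale < 1e-10) {
    stop_romval("points are collinear or coincident; plane is not unique",
                "romval_geometry_error")
  }
  n <- sv$v[, 3L]
  i <- which.max(abs(n))
  if (n[i] < 0) n <- -n
  list(normal = n, centroid = ctr, rss = sv$d[3L]^2)
}

#' Fit a plane normal by consensus (RANSAC) with a total-least-squares refit
#'
#' Finds the unit normal of the consensus plane through `points`. Candidate
#' planes are exact fits to point triples; the candidate with the most
#' inliers (perpendicular distance below `residual_threshold`) wins, ties
#' broken by the smaller inlier residual sum. The final normal is the
#' total-least-squares plane of the winning inlier set, so with four or fewer
#' points whose residuals are all below threshold the result equals the TLS
#' plane of all points. If no valid triple exists the fit falls back to TLS
#' on all points. The sign of the returned normal is unresolved (normalized
#' to a positive leading component); callers pick the anatomically meaningful
#' sign.
#'
#' @param points numeric matrix with one 3D point per row (>= 3 rows), or a
#'   list of 3-vectors.
#' @param params a [plane_fit_params()].
#' @return unit 3-vector (plane normal).
#' @export
fit_plane_normal <- function(points, params = plane_fit_params()) {
  if (is.list(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) < 3L) {
    stop_romval("plane fit needs at least 3 points", "romval_validation_error")
  }
  if (!all(is.finite(points))) {
    stop_romval("plane fit points must be finite", "romval_validation_error")
  }
  n_pts <- nrow(points)
  triples <- utils::combn(n_pts, 3L)
  if (ncol(triples) > params$max_trials) {
    # subsample candidate triples deterministically
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(params$random_seed)
    triples <- triples[, sample.int(ncol(triples), params$max_trials), drop = FALSE]
  }
  best <- NULL
  for (j in seq_len(ncol(triples))) {
    idx <- triples[, j]
    p1 <- points[idx[1L], ]; p2 <- points[idx[2L], ]; p3 <- points[idx[3L], ]
    nrm <- cross3(p2 - p1, p3 - p1)
    if (vnorm(nrm) < 1e-12) next  # degenerate triple
    nrm <- nrm / vnorm(nrm)
    d <- abs(as.vector((points - matrix(p1, n_pts, 3L, byrow = TRUE)) %*% nrm))
    inl <- d < params$residual_threshold
    if (sum(inl) < params$min_samples) next
    score <- c(sum(inl), -sum(d[inl]^2))
    if (is.null(best) || score[1L] > best$score[1L] ||
        (score[1L] == best$score[1L] && score[2L] > best$score[2L])) {
      best <- list(score = score, inliers = inl)
    }
  }
  if (is.null(best)) {
    # no consensus (e.g. all triples degenerate w.r.t. threshold): TLS on all
    return(tls_plane(points)$normal)
  }
  tls_plane(points[best$inliers, , drop = FALSE])$normal
}

#' Virtual anatomical coordinate frame
#'
#' Construct the camera-invariant anatomical frame from the four torso
#' keypoints. The origin is the midpoint between the hips. The Y axis
#' (transverse-plane normal) is the unit vector from the shoulders' midpoint
#' to the hips' midpoint, i.e. it points caudally ("down" for an upright
#' subject). The Z axis (frontal-plane normal) is the consensus-plane normal
#' of the four torso points, re-orthogonalized against Y (Y is the more
#' direct anatomical measurement, so it is kept exact and Z is projected and
#' renormalized), with its sign chosen to have a positive dot product with
#' `anterior_hint`. The X axis (sagittal-plane normal) follows from the
#' right-hand rule, `x = y x z`.
#'
#' @param shoulder_l,shoulder_r,hip_l,hip_r finite 3-vectors (meters).
#' @param params a [plane_fit_params()].
#' @param anterior_hint 3-vector with a positive component along the
#'   subject's anterior direction, used only to disambiguate the sign of the
#'   fitted plane normal. The default `c(0, 0, 1)` suits a camera placed in
#'   front of the subject (|yaw| < 90 degrees) in the raw stream convention.
#' @return an object of class `anatomical_frame` with fields `origin`,
#'   `x_axis`, `y_axis`, `z_axis` (unit, pairwise orthogonal, right-handed).
#' @export
build_anatomical_frame <- function(shoulder_l, shoulder_r, hip_l, hip_r,
                                   params = plane_fit_params(),
                                   anterior_hint = c(0, 0, 1)) {
  pts <- lapply(list(shoulder_l, shoulder_r, hip_l, hip_r),
                function(p) unname(as.vector(p)))
  if (!all(vapply(pts, is_finite_vec3, logical(1L)))) {
    stop_romval("torso keypoints must be finite 3-vectors", "romval_validation_error")
  }
  shoulder_l <- pts[[1L]]; shoulder_r <- pts[[2L]]
  hip_l <- pts[[3L]]; hip_r <- pts[[4L]]
  sh_mid <- (shoulder_l + shoulder_r) / 2
  hip_mid <- (hip_l + hip_r) / 2
  if (vnorm(hip_mid - sh_mid) < 1e-9) {
    stop_romval("shoulders midpoint coincides with hips midpoint",
                "romval_geometry_error")
  }
  y <- unitize(hip_mid - sh_mid)
  z_raw <- fit_plane_normal(do.call(rbind, pts), params)
  z_perp <- z_raw - sum(z_raw * y) * y
  if (vnorm(z_perp) < 1e-9) {
    stop_romval("fitted frontal-plane normal is parallel to the longitudinal axis",
                "romval_geometry_error")
  }
  z <- unitize(z_perp)
  if (sum(z * anterior_hint) < 0) z <- -z  # anterior sign convention
  x <- cross3(y, z)
  structure(
    list(origin = hip_mid, x_axis = x, y_axis = y, z_axis = z),
    class = "anatomical_frame"
  )
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n")
  cat(sprintf("  origin (m): % .4f % .4f % .4f\n", x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis")) {
    cat(sprintf("  %s: % .4f % .4f % .4f\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  }
  invisible(x)
}

#' The identity anatomical frame (origin 0, global axes)
#' @return an `anatomical_frame`.
#' @export
identity_frame <- function() {
  structure(
    list(origin = c(0, 0, 0), x_axis = c(1, 0, 0), y_axis = c(0, 1, 0),
         z_axis = c(0, 0, 1)),
    class = "anatomical_frame"
  )
}

#' Express a trajectory in an anatomical frame
#'
#' Maps every position `p` to `((p - origin) . x, (p - origin) . y,
#' (p - origin) . z)`. Frame rate, landmark set and missingness are
#' preserved. After the transform, +y is the caudal ("down") direction, +z
#' anterior, and x the sagittal-plane normal.
#'
#' @param traj a [landmark_trajectory()].
#' @param frame an `anatomical_frame`.
#' @return a [landmark_trajectory()] in frame coordinates.
#' @export
transform_to_frame <- function(traj, frame) {
  if (!inherits(frame, "anatomical_frame")) {
    stop_romval("frame must be an anatomical_frame", "romval_validation_error")
  }
  R <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)  # columns = new axes
  dims <- dim(traj$positions)
  flat <- matrix(traj$positions, nrow = dims[1L] * dims[2L], ncol = 3L)
  flat <- sweep(flat, 2L, frame$origin)
  out <- flat %*% R
  pos <- array(out, dim = dims)
  landmark_trajectory(pos, traj$skeleton, traj$fps)
}

#' Build the anatomical frame from the first fully visible torso frame
#'
#' Scans the trajectory for the first frame in which both shoulders and both
#' hips are non-missing and builds a single static frame from it; that frame
#' is used for the whole acquisition.
#'
#' @inheritParams transform_to_frame
#' @param params a [plane_fit_params()].
#' @param anterior_hint see [build_anatomical_frame()].
#' @return an `anatomical_frame`.
#' @export
frame_from_first_visible <- function(traj, params = plane_fit_params(),
                                     anterior_hint = c(0, 0, 1)) {
  joints <- c("shoulder_l", "shoulder_r", "hip_l", "hip_r")
  mats <- lapply(joints, function(j) joint_positions(traj, j))
  ok <- Reduce(`&`, lapply(mats, function(m) stats::complete.cases(m)))
  idx <- which(ok)
  if (!length(idx)) {
    stop_romval("no frame has all four torso landmarks visible", "romval_data_error")
  }
  f <- idx[1L]
  build_anatomical_frame(mats[[1L]][f, ], mats[[2L]][f, ],
                         mats[[3L]][f, ], mats[[4L]][f, ],
                         params = params, anterior_hint = anterior_hint)
}

#' Map a ground-truth stream into the anatomical axis convention
#'
#' Optical motion-capture axes are assumed parallel to the anatomical plane
#' normals, so instead of re-fitting a frame the stream is converted by a
#' config-level axis mapping: name which global axis points caudally (down)
#' and which points anteriorly. Axes are given as signed axis labels
#' (`"+y"`, `"-z"`, ...).
#'
#' @param traj a [landmark_trajectory()].
#' @param down_axis signed axis label of the caudal direction (default "+y").
#' @param anterior_axis signed axis label of the anterior direction
#'   (default "+z").
#' @param origin optional 3-vector subtracted before the axis mapping.
#' @return a [landmark_trajectory()] in the anatomical convention
#'   (+y down, +z anterior, x = y cross z).
#' @export
apply_axis_convention <- function(traj, down_axis = "+y", anterior_axis = "+z",
                                  origin = c(0, 0, 0)) {
  y <- parse_axis_label(down_axis)
  z <- parse_axis_label(anterior_axis)
  if (abs(sum(y * z)) > 1e-12) {
    stop_romval("down_axis and anterior_axis must be orthogonal", "romval_validation_error")
  }
  frame <- structure(
    list(origin = origin, x_axis = cross3(y, z), y_axis = y, z_axis = z),
    class = "anatomical_frame"
  )
  transform_to_frame(traj, frame)
}

parse_axis_label <- function(label) {
  m <- regmatches(label, regexec("^([+-]?)([xyz])$", label))[[1L]]
  if (length(m) != 3L) {
    stop_romval(paste0("invalid axis label '", label, "' (use e.g. '+y', '-z')"),
                "romval_validation_error")
  }
  sgn <- if (m[2L] == "-") -1 else 1
  v <- c(x = 1L, y = 2L, z = 3L)[[m[3L]]]
  out <- c(0, 0, 0); out[v] <- sgn
  out
}
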