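#' Exercise protocol specification
#'
#' The acquisition protocol emulated by the generator: `n_sets` sets of
#' `reps_per_set` repetitions with a rest of `rest_s` seconds between sets.
#' Each repetition is a raised-cosine amplitude pulse 0 -> peak -> 0 lasting
#' `rep_period_s` seconds; per-repetition peak heights are perturbed by
#' independent Gaussian jitter to emulate human rep-to-rep variability.
#'
#' @param n_sets number of sets (default 2).
#' @param reps_per_set repetitions per set (default 7).
#' @param rest_s resting period between sets in seconds (default 10).
#' @param rep_period_s duration of one repetition in seconds (default 3).
#' @param peak_amplitude_deg nominal peak amplitude in degrees (default 90).
#' @param per_rep_jitter_deg standard deviation of the per-repetition peak
#'   jitter in degrees (default 3).
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_sets = 2L, reps_per_set = 7L, rest_s = 10,
                          peak_amplitude_deg = 90, rep_period_s = 3,
                          per_rep_jitter_deg = 3) {
  if (n_sets < 1L || reps_per_set < 1L) {
    stop_romval("counts must be >= 1", "romval_validation_error")
  }
  if (rest_s <= 0 || rep_period_s <= 0) {
    stop_romval("durations must be > 0", "romval_validation_error")
  }
  if (peak_amplitude_deg <= 0 || peak_amplitude_deg > 180) {
    stop_romval("peak_amplitude_deg must be in (0, 180]", "romval_validation_error")
  }
  structure(
    list(n_sets = as.integer(n_sets), reps_per_set = as.integer(reps_per_set),
         rest_s = rest_s, rep_period_s = rep_period_s,
         peak_amplitude_deg = peak_amplitude_deg,
         per_rep_jitter_deg = per_rep_jitter_deg),
    class = "protocol_spec"
  )
}

#' Camera / acquisition model for the predicted stream
#'
#' Describes how the synthetic predicted stream deviates from the ground
#' truth: the camera yaw about the vertical (longitudinal) axis (0 for
#' frontal-plane exercises, commonly 35 degrees for sagittal ones, matching a
#' camera placed to minimize occlusions), isotropic landmark position noise,
#' a linear amplitude distortion such that
#' `ground_truth_angle = amp_slope * predicted_angle + amp_intercept_deg`
#' holds exactly on noiseless data, additive Gaussian noise on the predicted
#' angle itself, an unknown start-time offset between the streams (the
#' predicted recording starts `start_offset_s` seconds after the ground
#' truth), and the video frame rate.
#'
#' @param yaw_deg camera yaw in degrees (default 0).
#' @param noise_sigma_m landmark position noise SD in meters (default 0).
#' @param amp_slope,amp_intercept_deg linear amplitude distortion (defaults
#'   1 and 0 = no distortion).
#' @param start_offset_s start-time offset in seconds (default 0).
#' @param fps predicted stream frame rate (default 30).
#' @param angle_noise_sd_deg additive angle noise SD in degrees (default 0).
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(yaw_deg = 0, noise_sigma_m = 0, amp_slope = 1,
                         amp_intercept_deg = 0, start_offset_s = 0,
                         fps = 30, angle_noise_sd_deg = 0) {
  if (fps <= 0) stop_romval("fps must be > 0", "romval_validation_error")
  if (noise_sigma_m < 0 || angle_noise_sd_deg < 0) {
    stop_romval("noise magnitudes must be >= 0", "romval_validation_error")
  }
  if (start_offset_s < 0) {
    stop_romval("start_offset_s must be >= 0", "romval_validation_error")
  }
  structure(
    list(yaw_deg = yaw_deg, noise_sigma_m = noise_sigma_m,
         amp_slope = amp_slope, amp_intercept_deg = amp_intercept_deg,
         start_offset_s = start_offset_s, fps = fps,
         angle_noise_sd_deg = angle_noise_sd_deg),
    class = "camera_model"
  )
}

#' Body segment-length template
#'
#' Plausible adult segment lengths (meters) used by the forward-kinematic
#' poser. Amplitudes are invariant to uniform scaling, so these only matter
#' for how positional noise converts into angular noise (longer segments
#' attenuate it).
#'
#' @param shoulder_width,hip_width,torso_height,upper_arm,forearm,thigh,shank
#'   segment lengths in meters, all positive.
#' @return an object of class `body_template`.
#' @export
body_template <- function(shoulder_width = 0.35, hip_width = 0.20,
                          torso_height = 0.50, upper_arm = 0.30,
                          forearm = 0.27, thigh = 0.42, shank = 0.40) {
  vals <- c(shoulder_width, hip_width, torso_height, upper_arm, forearm,
            thigh, shank)
  if (any(vals <= 0)) stop_romval("segment lengths must be > 0", "romval_validation_error")
  structure(
    list(shoulder_width = shoulder_width, hip_width = hip_width,
         torso_height = torso_height, upper_arm = upper_arm,
         forearm = forearm, thigh = thigh, shank = shank),
    class = "body_template"
  )
}

# Neutral canonical joint positions in the anatomical convention
# (+y caudal/down, +z anterior, +x = subject's right; origin = mid-hips).
neutral_joints <- function(tpl) {
  sw <- tpl$shoulder_width / 2; hw <- tpl$hip_width / 2
  j <- list(
    shoulder_r = c(sw, -tpl$torso_height, 0),
    shoulder_l = c(-sw, -tpl$torso_height, 0),
    hip_r = c(hw, 0, 0), hip_l = c(-hw, 0, 0)
  )
  j$elbow_r <- j$shoulder_r + c(0, tpl$upper_arm, 0)
  j$elbow_l <- j$shoulder_l + c(0, tpl$upper_arm, 0)
  j$wrist_r <- j$elbow_r + c(0, tpl$forearm, 0)
  j$wrist_l <- j$elbow_l + c(0, tpl$forearm, 0)
  j$knee_r <- j$hip_r + c(0, tpl$thigh, 0)
  j$knee_l <- j$hip_l + c(0, tpl$thigh, 0)
  j$ankle_r <- j$knee_r + c(0, tpl$shank, 0)
  j$ankle_l <- j$knee_l + c(0, tpl$shank, 0)
  j
}

# Per-frame canonical joint positions for a vector of amplitudes (degrees,
# may be negative: the limb swings through the zero position, and the
# unsigned measurement folds it back). Returns list of n x 3 matrices.
# Only the joints involved in the exercise move; bilateral exercises mirror
# the motion onto the left side.
pose_joints <- function(tpl, cfg, angles_deg) {
  th <- deg2rad(angles_deg)
  n <- length(th)
  jn <- neutral_joints(tpl)
  J <- lapply(jn, function(p) matrix(rep(p, each = n), nrow = n))
  down <- c(0, 1, 0); ant <- c(0, 0, 1); lat <- c(1, 0, 0)
  dirmat <- function(a, b) outer(cos(th), a) + outer(sin(th), b)
  move_arm <- function(side, dir) {
    sh <- paste0("shoulder_", side)
    J[[paste0("elbow_", side)]] <<- J[[sh]] + tpl$upper_arm * dir
    J[[paste0("wrist_", side)]] <<- J[[sh]] + (tpl$upper_arm + tpl$forearm) * dir
  }
  switch(cfg$code,
    SF = move_arm("r", dirmat(down, ant)),
    SA = move_arm("r", dirmat(down, lat)),
    SP = { move_arm("r", dirmat(down, lat)); move_arm("l", dirmat(down, -lat)) },
    EF = {
      for (side in c("r", "l")) {
        el <- paste0("elbow_", side)
        J[[paste0("wrist_", side)]] <- J[[el]] + tpl$forearm * dirmat(down, ant)
      }
    },
    HA = {
      dir <- dirmat(down, lat)
      J$knee_r <- J$hip_r + tpl$thigh * dir
      J$ankle_r <- J$hip_r + (tpl$thigh + tpl$shank) * dir
    },
    MCH = {
      J$knee_r <- J$hip_r + tpl$thigh * dirmat(down, ant)
      J$ankle_r <- J$knee_r + outer(rep(tpl$shank, n), down)
    },
    SQ = {
      for (side in c("r", "l")) {
        hp <- paste0("hip_", side)
        kn <- paste0("knee_", side)
        J[[kn]] <- J[[hp]] + tpl$thigh * dirmat(down, -ant)
        J[[paste0("ankle_", side)]] <- J[[kn]] + outer(rep(tpl$shank, n), down)
      }
    },
    SKF = {
      J$knee_r <- J$hip_r + tpl$thigh * matrix(rep(ant, each = n), nrow = n)
      J$ankle_r <- J$knee_r + tpl$shank * dirmat(down, ant)
    },
    stop_romval(paste0("unknown exercise code '", cfg$code, "'"),
                "romval_config_error")
  )
  J
}

# Fixed offsets (meters) of the non-joint predicted-skeleton landmarks,
# relative to an anchor joint; cosmetic, but keeps all 33 landmarks present.
MP_EXTRAS <- list(
  nose = list(anchor = "mid_shoulder", off = c(0, -0.12, 0.08)),
  left_eye_inner = list(anchor = "mid_shoulder", off = c(-0.015, -0.16, 0.07)),
  left_eye = list(anchor = "mid_shoulder", off = c(-0.03, -0.16, 0.065)),
  left_eye_outer = list(anchor = "mid_shoulder", off = c(-0.045, -0.16, 0.06)),
  right_eye_inner = list(anchor = "mid_shoulder", off = c(0.015, -0.16, 0.07)),
  right_eye = list(anchor = "mid_shoulder", off = c(0.03, -0.16, 0.065)),
  right_eye_outer = list(anchor = "mid_shoulder", off = c(0.045, -0.16, 0.06)),
  left_ear = list(anchor = "mid_shoulder", off = c(-0.07, -0.15, 0.0)),
  right_ear = list(anchor = "mid_shoulder", off = c(0.07, -0.15, 0.0)),
  mouth_left = list(anchor = "mid_shoulder", off = c(-0.02, -0.10, 0.08)),
  mouth_right = list(anchor = "mid_shoulder", off = c(0.02, -0.10, 0.08)),
  left_pinky = list(anchor = "wrist_l", off = c(-0.01, 0.08, 0.01)),
  right_pinky = list(anchor = "wrist_r", off = c(0.01, 0.08, 0.01)),
  left_index = list(anchor = "wrist_l", off = c(-0.01, 0.08, 0.03)),
  right_index = list(anchor = "wrist_r", off = c(0.01, 0.08, 0.03)),
  left_thumb = list(anchor = "wrist_l", off = c(0.0, 0.06, 0.04)),
  right_thumb = list(anchor = "wrist_r", off = c(0.0, 0.06, 0.04)),
  left_heel = list(anchor = "ankle_l", off = c(0, 0.05, -0.05)),
  right_heel = list(anchor = "ankle_r", off = c(0, 0.05, -0.05)),
  left_foot_index = list(anchor = "ankle_l", off = c(0, 0.07, 0.13)),
  right_foot_index = list(anchor = "ankle_r", off = c(0, 0.07, 0.13))
)

# Assemble a full positions array for one skeleton from canonical joint
# position matrices.
assemble_positions <- function(J, skeleton) {
  n <- nrow(J$hip_r)
  lms <- skeleton$landmarks
  pos <- array(NA_real_, dim = c(n, length(lms), 3L))
  inv_map <- stats::setNames(names(skeleton$joint_map), unname(skeleton$joint_map))
  anchors <- c(J, list(mid_shoulder = (J$shoulder_r + J$shoulder_l) / 2))
  for (k in seq_along(lms)) {
    lm <- lms[k]
    if (!is.na(inv_map[lm])) {
      pos[, k, ] <- J[[inv_map[lm]]]
    } else if (!is.null(MP_EXTRAS[[lm]])) {
      ex <- MP_EXTRAS[[lm]]
      pos[, k, ] <- anchors[[ex$anchor]] +
        matrix(rep(ex$off, each = n), nrow = n)
    } else {
      stop_romval(paste0("cannot place landmark '", lm, "'"), "romval_config_error")
    }
  }
  pos
}

#' Continuous-time repetition angle profile
#'
#' Builds the driving joint-angle profile of a protocol: raised-cosine pulses
#' `0 -> peak -> 0` for each repetition, zero during rest. Per-repetition
#' peaks are perturbed by `per_rep_jitter_deg` Gaussian jitter drawn from
#' `seed` (the global RNG state is left untouched). The profile is evaluable
#' at arbitrary times.
#'
#' @param protocol a [protocol_spec()].
#' @param seed integer seed for the jitter.
#' @return list with `fn` (vectorized function of time in seconds ->
#'   degrees), `peak_times` (s), `peak_amps` (deg), `duration` (s).
#' @export
angle_profile <- function(protocol, seed = 1L) {
  p <- protocol
  n_reps <- p$n_sets * p$reps_per_set
  jit <- with_local_seed(seed, stats::rnorm(n_reps, 0, p$per_rep_jitter_deg))
  amps <- pmin(180, pmax(1e-3, p$peak_amplitude_deg + jit))
  set_len <- p$reps_per_set * p$rep_period_s
  starts <- as.vector(vapply(seq_len(p$n_sets), function(i) {
    (i - 1L) * (set_len + p$rest_s) + (seq_len(p$reps_per_set) - 1L) * p$rep_period_s
  }, numeric(p$reps_per_set)))
  duration <- p$n_sets * set_len + (p$n_sets - 1L) * p$rest_s
  fn <- function(t) {
    out <- numeric(length(t))
    for (k in seq_along(starts)) {
      inside <- t >= starts[k] & t < starts[k] + p$rep_period_s
      if (any(inside)) {
        ph <- (t[inside] - starts[k]) / p$rep_period_s
        out[inside] <- amps[k] / 2 * (1 - cos(2 * pi * ph))
      }
    }
    out
  }
  list(fn = fn, peak_times = starts + p$rep_period_s / 2, peak_amps = amps,
       duration = duration)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pose both skeletons at a given joint amplitude
#'
#' Places the moving body segment of the exercise so that the amplitude
#' measurement applied to the returned pose recovers `angle` exactly; all
#' other joints stay in the neutral pose, with the torso coplanar. This is
#' the inverse of the measurement and the generator's defining property.
#'
#' @param template a [body_template()].
#' @param cfg an `exercise_config` (or code).
#' @param angle amplitude in degrees, in `[0, 180]`.
#' @return list with `gt` (6 x 3 marker matrix, marker-set skeleton) and
#'   `pred` (33 x 3 landmark matrix), rows named, in the anatomical
#'   convention.
#' @export
pose_from_angle <- function(template, cfg, angle) {
  if (is.character(cfg)) cfg <- exercise_config(cfg)
  if (!is.numeric(angle) || length(angle) != 1L || is.na(angle) ||
      angle < 0 || angle > 180) {
    stop_romval("angle must be a scalar in [0, 180] degrees", "romval_validation_error")
  }
  J <- pose_joints(template, cfg, angle)
  gt_sk <- mocap_skeleton(); mp_sk <- mediapipe_skeleton()
  gt <- assemble_positions(J, gt_sk)[1L, , ]
  pred <- assemble_positions(J, mp_sk)[1L, , ]
  rownames(gt) <- gt_sk$landmarks; rownames(pred) <- mp_sk$landmarks
  list(gt = gt, pred = pred)
}

rotation_about_y <- function(deg) {
  a <- deg2rad(deg)
  # +y is "down"; a positive yaw turns the subject about the longitudinal axis
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3L, 3L, byrow = TRUE)
}

rotate_positions <- function(pos, R) {
  dims <- dim(pos)
  flat <- matrix(pos, nrow = dims[1L] * dims[2L], ncol = 3L)
  array(flat %*% t(R), dim = dims)
}

#' Render a paired synthetic acquisition
#'
#' Generates the two simultaneously recorded streams of one acquisition:
#'
#' * ground truth: the angle profile, mapped through the linear amplitude
#'   relation `gt_angle = amp_slope * profile + amp_intercept_deg` (clamped
#'   to `[0, 180]`), sampled at 100 FPS and posed on the 6-marker skeleton in
#'   the anatomical-aligned laboratory frame. Injecting the linear distortion
#'   on this side keeps the predicted amplitudes in `[0, 180]` for any
#'   profile, so the linear relation between the streams is exactly
#'   recoverable (posing a negative angle would fold it back into the
#'   unsigned range and bend the relation near zero).
#' * predicted: the raw angle profile plus per-sample Gaussian angle noise,
#'   started `start_offset_s` seconds late, sampled at `camera$fps`, posed on
#'   the 33-landmark skeleton, rotated by the camera yaw about the vertical
#'   (shoulders-to-hips) axis, and perturbed with isotropic Gaussian
#'   positional noise per landmark coordinate.
#'
#' Identical seeds give bit-identical acquisitions.
#'
#' @param template a [body_template()].
#' @param cfg an `exercise_config` or code.
#' @param protocol a [protocol_spec()].
#' @param camera a [camera_model()].
#' @param seed integer seed controlling every random draw.
#' @param gt_fps ground-truth frame rate (default 100).
#' @param subject_id identifier stored on the pair.
#' @return an [acquisition_pair()] with attribute `truth`: list of the
#'   generating parameters (profile peak times/amplitudes, offset, slope,
#'   intercept, yaw, noise levels) for use as a test oracle.
#' @export
render_pair <- function(template, cfg, protocol = protocol_spec(),
                        camera = camera_model(), seed = 1L, gt_fps = 100,
                        subject_id = "synthetic") {
  if (is.character(cfg)) cfg <- exercise_config(cfg)
  prof <- angle_profile(protocol, seed)
  # ground truth stream
  gt_t <- seq(0, prof$duration, by = 1 / gt_fps)
  gt_angles <- pmin(180, pmax(0, camera$amp_slope * prof$fn(gt_t) +
                                camera$amp_intercept_deg))
  gt_pos <- assemble_positions(pose_joints(template, cfg, gt_angles),
                               mocap_skeleton())
  gt_traj <- landmark_trajectory(gt_pos, mocap_skeleton(), gt_fps)
  # predicted stream (starts start_offset_s after the ground truth)
  pr_t_local <- seq(0, max(0, prof$duration - camera$start_offset_s),
                    by = 1 / camera$fps)
  pr_true <- prof$fn(pr_t_local + camera$start_offset_s)
  noise <- with_local_seed(seed + 1000003L, list(
    angle = stats::rnorm(length(pr_t_local), 0, camera$angle_noise_sd_deg),
    pos = stats::rnorm(length(pr_t_local) * 33L * 3L, 0, 1)
  ))
  pr_angles <- pr_true + noise$angle
  pr_pos <- assemble_positions(pose_joints(template, cfg, pr_angles),
                               mediapipe_skeleton())
  pr_pos <- rotate_positions(pr_pos, rotation_about_y(camera$yaw_deg))
  if (camera$noise_sigma_m > 0) {
    pr_pos <- pr_pos + array(noise$pos * camera$noise_sigma_m, dim = dim(pr_pos))
  }
  pr_traj <- landmark_trajectory(pr_pos, mediapipe_skeleton(), camera$fps)
  pair <- acquisition_pair(gt_traj, pr_traj, cfg, subject_id)
  attr(pair, "truth") <- list(
    peak_times = prof$peak_times, peak_amps = prof$peak_amps,
    duration = prof$duration, start_offset_s = camera$start_offset_s,
    amp_slope = camera$amp_slope, amp_intercept_deg = camera$amp_intercept_deg,
    yaw_deg = camera$yaw_deg, noise_sigma_m = camera$noise_sigma_m,
    angle_noise_sd_deg = camera$angle_noise_sd_deg, seed = seed
  )
  pair
}

#' Write a synthetic acquisition to disk
#'
#' Writes `gt.csv`, `pred.csv` (the wide-table trajectory dialect) and
#' `manifest.json` (the generating parameters, i.e. the test oracle) into
#' `dir`.
#'
#' @param pair an [acquisition_pair()] from [render_pair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_acquisition <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(pair$ground_truth, file.path(dir, "gt.csv"))
  write_trajectory(pair$predicted, file.path(dir, "pred.csv"))
  manifest <- c(list(exercise = pair$exercise$code,
                     subject_id = pair$subject_id,
                     gt_fps = pair$ground_truth$fps,
                     pred_fps = pair$predicted$fps),
                attr(pair, "truth"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
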