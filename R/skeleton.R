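#' Skeleton definitions
#'
#' A skeleton definition names an ordered landmark set and maps canonical
#' joint names (`shoulder_r`, `elbow_r`, ..., plus left-side variants where
#' available) onto landmark names. Two definitions ship with the package:
#' the 33-landmark monocular pose-estimation skeleton and the 6-marker
#' right-side motion-capture marker set (acromion, lateral epicondyle of the
#' humerus, radial styloid, greater trochanter, lateral femoral epicondyle,
#' lateral malleolus).
#'
#' @param name identifier for the skeleton.
#' @param landmarks character vector of unique landmark names.
#' @param joint_map named character vector/list mapping canonical joint names
#'   to landmark names; every value must be a landmark.
#' @return An object of class `skeleton_definition`.
#' @examples
#' sk <- skeleton_definition("toy", c("a", "b"), c(shoulder_r = "a", elbow_r = "b"))
#' resolve_joint(sk, "shoulder_r")
#' @export
skeleton_definition <- function(name, landmarks, joint_map) {
  landmarks <- as.character(landmarks)
  if (anyDuplicated(landmarks)) {
    stop_romval("skeleton landmark names must be unique", "romval_validation_error")
  }
  joint_map <- unlist(joint_map)
  if (is.null(names(joint_map)) || any(names(joint_map) == "")) {
    stop_romval("joint_map must be a named mapping", "romval_validation_error")
  }
  missing <- setdiff(unname(joint_map), landmarks)
  if (length(missing)) {
    stop_romval(
      paste0("joint_map refers to unknown landmarks: ", paste(missing, collapse = ", ")),
      "romval_validation_error"
    )
  }
  structure(
    list(name = as.character(name), landmarks = landmarks,
         joint_map = joint_map),
    class = "skeleton_definition"
  )
}

#' @export
print.skeleton_definition <- function(x, ...) {
  cat("<skeleton_definition>", x$name, "-", length(x$landmarks), "landmarks,",
      length(x$joint_map), "mapped joints\n")
  invisible(x)
}

#' Resolve a canonical joint name to a landmark name
#'
#' @param skeleton a [skeleton_definition()].
#' @param joint canonical joint name (e.g. `"knee_r"`).
#' @return landmark name (character scalar).
#' @export
resolve_joint <- function(skeleton, joint) {
  lm <- skeleton$joint_map[[joint]]
  if (is.null(lm)) {
    stop_romval(paste0("joint '", joint, "' is not mapped in skeleton '",
                       skeleton$name, "'"), "romval_config_error")
  }
  lm
}

# The 33 landmark names of the monocular pose-estimation skeleton, in model
# output order.
MEDIAPIPE_LANDMARKS <- c(
  "nose",
  "left_eye_inner", "left_eye", "left_eye_outer",
  "right_eye_inner", "right_eye", "right_eye_outer",
  "left_ear", "right_ear",
  "mouth_left", "mouth_right",
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist",
  "left_pinky", "right_pinky",
  "left_index", "right_index",
  "left_thumb", "right_thumb",
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_ankle", "right_ankle",
  "left_heel", "right_heel",
  "left_foot_index", "right_foot_index"
)

#' Built-in skeleton: 33-landmark predicted pose skeleton
#'
#' @return a [skeleton_definition()] with 33 landmarks and canonical joint
#'   mappings for both body sides.
#' @export
mediapipe_skeleton <- function() {
  skeleton_definition(
    "mediapipe33", MEDIAPIPE_LANDMARKS,
    c(shoulder_r = "right_shoulder", shoulder_l = "left_shoulder",
      elbow_r = "right_elbow", elbow_l = "left_elbow",
      wrist_r = "right_wrist", wrist_l = "left_wrist",
      hip_r = "right_hip", hip_l = "left_hip",
      knee_r = "right_knee", knee_l = "left_knee",
      ankle_r = "right_ankle", ankle_l = "left_ankle")
  )
}

#' Built-in skeleton: 6-marker right-side motion-capture marker set
#'
#' Markers sit on bony landmarks of the right side: acromion (shoulder),
#' lateral epicondyle of the humerus (elbow), styloid apophysis of the radius
#' (wrist), greater trochanter (hip), lateral epicondyle of the femur (knee),
#' and lateral malleolus (ankle).
#'
#' @return a [skeleton_definition()] with 6 markers.
#' @export
mocap_skeleton <- function() {
  skeleton_definition(
    "mocap6",
    c("acromion_r", "lat_epicondyle_humerus_r", "radial_styloid_r",
      "greater_trochanter_r", "lat_epicondyle_femur_r", "lat_malleolus_r"),
    c(shoulder_r = "acromion_r", elbow_r = "lat_epicondyle_humerus_r",
      wrist_r = "radial_styloid_r", hip_r = "greater_trochanter_r",
      knee_r = "lat_epicondyle_femur_r", ankle_r = "lat_malleolus_r")
  )
}

#' Serialize / deserialize a skeleton definition as JSON
#'
#' @param skeleton a [skeleton_definition()].
#' @param path file path.
#' @return `read_skeleton_json` returns a [skeleton_definition()];
#'   `write_skeleton_json` returns the path, invisibly.
#' @export
write_skeleton_json <- function(skeleton, path) {
  jsonlite::write_json(
    list(name = skeleton$name, landmarks = skeleton$landmarks,
         joint_map = as.list(skeleton$joint_map)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_skeleton_json
#' @export
read_skeleton_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  skeleton_definition(x$name, x$landmarks, unlist(x$joint_map))
}
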