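#' Built-in exercise registry
#'
#' The eight musculoskeletal physiotherapy exercises supported by the
#' pipeline, each with its plane of movement, body segment (evaluated joint
#' to the closest joint of the moving limb), reference direction (the 0-degree
#' "neutral zero" position) and evaluated joint:
#'
#' | code | exercise                      | plane    | segment         | reference  | evaluated joint |
#' |------|-------------------------------|----------|-----------------|------------|-----------------|
#' | SF   | shoulder flexion/extension    | sagittal | shoulder->elbow | down       | right shoulder  |
#' | SA   | shoulder abduction/adduction  | frontal  | shoulder->elbow | down       | right shoulder  |
#' | EF   | elbow flexion/extension       | sagittal | elbow->wrist    | down       | right elbow     |
#' | SP   | shoulder press                | frontal  | shoulder->elbow | down       | right shoulder  |
#' | HA   | hip abduction/adduction       | frontal  | hip->knee       | down       | right hip       |
#' | SQ   | squat                         | sagittal | knee->hip       | foot->knee | right knee      |
#' | MCH  | march                         | sagittal | hip->knee       | down       | right hip       |
#' | SKF  | seated knee flexion/extension | sagittal | knee->foot      | down       | right knee      |
#'
#' "down" is the constant caudal direction (+y of the anatomical convention);
#' the squat reference is the dynamic per-frame foot->knee vector. "foot"
#' uses the ankle landmark in both skeletons (the most distal marker of the
#' marker set is the lateral malleolus, and the ankle is its homolog in the
#' predicted skeleton), configurable via the `joint1`/`joint2` fields. Only
#' the right body side is evaluated.
#'
#' @return named list of `exercise_config` objects, keyed by code.
#' @export
exercise_registry <- function() {
  reg <- list(
    SF  = list(name = "shoulder flexion/extension", plane = "sagittal",
               joint1 = "shoulder_r", joint2 = "elbow_r", reference = "down",
               evaluated_joint = "shoulder_r", moving_limb = "right arm"),
    SA  = list(name = "shoulder abduction/adduction", plane = "frontal",
               joint1 = "shoulder_r", joint2 = "elbow_r", reference = "down",
               evaluated_joint = "shoulder_r", moving_limb = "right arm"),
    EF  = list(name = "elbow flexion/extension", plane = "sagittal",
               joint1 = "elbow_r", joint2 = "wrist_r", reference = "down",
               evaluated_joint = "elbow_r", moving_limb = "arms (bilateral)"),
    SP  = list(name = "shoulder press", plane = "frontal",
               joint1 = "shoulder_r", joint2 = "elbow_r", reference = "down",
               evaluated_joint = "shoulder_r", moving_limb = "arms (bilateral)"),
    HA  = list(name = "hip abduction/adduction", plane = "frontal",
               joint1 = "hip_r", joint2 = "knee_r", reference = "down",
               evaluated_joint = "hip_r", moving_limb = "right leg"),
    SQ  = list(name = "squat", plane = "sagittal",
               joint1 = "knee_r", joint2 = "hip_r",
               reference = list(from = "ankle_r", to = "knee_r"),
               evaluated_joint = "knee_r", moving_limb = "legs (bilateral)"),
    MCH = list(name = "march", plane = "sagittal",
               joint1 = "hip_r", joint2 = "knee_r", reference = "down",
               evaluated_joint = "hip_r", moving_limb = "legs (bilateral)"),
    SKF = list(name = "seated knee flexion/extension", plane = "sagittal",
               joint1 = "knee_r", joint2 = "ankle_r", reference = "down",
               evaluated_joint = "knee_r", moving_limb = "right leg")
  )
  lapply(names(reg), function(code) {
    x <- reg[[code]]
    structure(c(list(code = code), x), class = "exercise_config")
  }) |> stats::setNames(names(reg))
}

#' Look up one exercise configuration
#'
#' @param code exercise code, one of SF, SA, EF, SP, HA, SQ, MCH, SKF.
#' @return an `exercise_config`.
#' @export
exercise_config <- function(code) {
  reg <- exercise_registry()
  cfg <- reg[[toupper(code)]]
  if (is.null(cfg)) {
    stop_romval(paste0("unknown exercise code '", code, "' (expected one of ",
                       paste(names(reg), collapse = ", "), ")"),
                "romval_config_error")
  }
  cfg
}

#' @export
print.exercise_config <- function(x, ...) {
  ref <- if (is.character(x$reference)) x$reference else
    paste0(x$reference$from, "->", x$reference$to)
  cat("<exercise_config>", x$code, "-", x$name, "\n")
  cat("  plane:", x$plane, " segment:", x$joint1, "->", x$joint2,
      " reference:", ref, "\n")
  invisible(x)
}

# Normal of the configured plane of movement, in the anatomical convention
# (frontal plane <=> z normal; sagittal plane <=> x normal).
plane_normal_of <- function(cfg) {
  switch(cfg$plane,
         frontal = c(0, 0, 1),
         sagittal = c(1, 0, 0),
         stop_romval(paste0("unsupported plane '", cfg$plane, "'"),
                     "romval_config_error"))
}
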