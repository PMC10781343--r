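#' Landmark trajectory container
#'
#' Time-indexed 3D positions (meters) for a named landmark set at a fixed
#' frame rate. Positions are stored as an `n_frames x n_landmarks x 3` array;
#' a missing landmark-frame pair is a row of `NA`s (never zero-filled, since
#' zero is a valid coordinate). All landmarks share the same frame index set.
#'
#' @param positions numeric array `n_frames x n_landmarks x 3`, with
#'   `dimnames[[2]]` equal to `skeleton$landmarks`; `NA` marks missing data.
#'   Partial `NA` within one landmark-frame triple is promoted to a fully
#'   missing triple.
#' @param skeleton a [skeleton_definition()].
#' @param fps frames per second (Hz, positive).
#' @return An object of class `landmark_trajectory`.
#' @export
landmark_trajectory <- function(positions, skeleton, fps) {
  if (!inherits(skeleton, "skeleton_definition")) {
    stop_romval("skeleton must be a skeleton_definition", "romval_validation_error")
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop_romval("fps must be a positive finite scalar", "romval_validation_error")
  }
  if (!is.array(positions) || length(dim(positions)) != 3L || dim(positions)[3] != 3L) {
    stop_romval("positions must be an n_frames x n_landmarks x 3 array",
                "romval_validation_error")
  }
  if (dim(positions)[1] < 1L) {
    stop_romval("trajectory needs at least one frame", "romval_validation_error")
  }
  if (dim(positions)[2] != length(skeleton$landmarks)) {
    stop_romval("positions second dimension must match the skeleton landmark count",
                "romval_validation_error")
  }
  dimnames(positions) <- list(NULL, skeleton$landmarks, c("x", "y", "z"))
  # promote partially-missing triples to fully missing
  na_any <- is.na(positions[, , 1L, drop = FALSE]) |
    is.na(positions[, , 2L, drop = FALSE]) | is.na(positions[, , 3L, drop = FALSE])
  if (any(na_any)) {
    for (k in 1:3) {
      slab <- positions[, , k]
      slab[na_any[, , 1L]] <- NA_real_
      positions[, , k] <- slab
    }
  }
  if (any(is.infinite(positions))) {
    stop_romval("positions must be finite or missing", "romval_validation_error")
  }
  structure(
    list(skeleton = skeleton, fps = fps, positions = positions,
         n_frames = dim(positions)[1]),
    class = "landmark_trajectory"
  )
}

#' @export
print.landmark_trajectory <- function(x, ...) {
  cat("<landmark_trajectory>", x$n_frames, "frames x",
      length(x$skeleton$landmarks), "landmarks @", x$fps, "FPS (",
      sprintf("%.2f", x$n_frames / x$fps), "s )\n")
  invisible(x)
}

#' Extract one landmark's positions over time
#'
#' @param traj a [landmark_trajectory()].
#' @param landmark landmark name.
#' @return an `n_frames x 3` matrix (rows of `NA` where missing).
#' @export
landmark_positions <- function(traj, landmark) {
  if (!landmark %in% traj$skeleton$landmarks) {
    stop_romval(paste0("unknown landmark '", landmark, "'"), "romval_validation_error")
  }
  traj$positions[, landmark, , drop = TRUE]
}

#' Positions of a canonical joint over time
#'
#' @inheritParams landmark_positions
#' @param joint canonical joint name, resolved through the skeleton joint map.
#' @export
joint_positions <- function(traj, joint) {
  landmark_positions(traj, resolve_joint(traj$skeleton, joint))
}

#' Read a landmark trajectory from a wide CSV/TSV table
#'
#' The file must be a wide table with a header row and three columns per
#' landmark named `<landmark>_x`, `<landmark>_y`, `<landmark>_z` (positions in
#' meters), one row per frame. The separator is auto-detected from the file
#' extension (`.tsv`/`.tab` = tab, anything else = comma). Empty cells become
#' missing positions.
#'
#' @param path file path.
#' @param skeleton a [skeleton_definition()] naming the landmarks expected in
#'   the file.
#' @param fps frame rate of the recording (Hz).
#' @return a [landmark_trajectory()].
#' @export
read_trajectory <- function(path, skeleton, fps) {
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0) {
    stop_romval("fps must be a positive scalar", "romval_validation_error")
  }
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  wanted <- as.vector(t(outer(skeleton$landmarks, c("_x", "_y", "_z"), paste0)))
  absent <- setdiff(wanted, names(df))
  if (length(absent)) {
    stop_romval(paste0("trajectory file is missing required columns: ",
                       paste(absent, collapse = ", ")), "romval_schema_error")
  }
  n <- nrow(df)
  if (n < 1L) stop_romval("trajectory file has no data rows", "romval_validation_error")
  pos <- array(NA_real_, dim = c(n, length(skeleton$landmarks), 3L))
  for (j in seq_along(skeleton$landmarks)) {
    for (k in 1:3) {
      col <- paste0(skeleton$landmarks[j], c("_x", "_y", "_z")[k])
      raw <- df[[col]]
      empty <- is.na(raw) | trimws(raw) == ""
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!empty & is.na(val))
      if (length(bad)) {
        stop_romval(paste0("non-numeric value in column '", col, "' at data row ",
                           bad[1L], ": '", raw[bad[1L]], "'"), "romval_parse_error")
      }
      val[empty] <- NA_real_
      pos[, j, k] <- val
    }
  }
  landmark_trajectory(pos, skeleton, fps)
}

#' Write a landmark trajectory to a wide CSV/TSV table
#'
#' Emits the dialect accepted by [read_trajectory()]; missing positions are
#' serialized as empty cells. Values are written with `format(..., digits =
#' 17)` so a write/read round trip reproduces positions bit-exactly.
#'
#' @param traj a [landmark_trajectory()].
#' @param path output file path; extension selects the separator.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  lms <- traj$skeleton$landmarks
  cols <- vector("list", length(lms) * 3L)
  nms <- character(length(lms) * 3L)
  i <- 0L
  for (j in seq_along(lms)) {
    for (k in 1:3) {
      i <- i + 1L
      v <- traj$positions[, j, k]
      s <- vapply(v, function(x) {
        if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1L))
      cols[[i]] <- s
      nms[i] <- paste0(lms[j], c("_x", "_y", "_z")[k])
    }
  }
  df <- as.data.frame(cols, col.names = nms, check.names = FALSE,
                      stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop_romval(paste0("cannot write trajectory to '", path, "': ",
                       conditionMessage(ok)), "romval_io_error")
  }
  invisible(path)
}

#' Paired acquisition: ground truth plus prediction
#'
#' Bundles the two simultaneously recorded streams of one acquisition: the
#' motion-capture marker stream (default 100 FPS) and the predicted skeleton
#' stream (default 30 FPS), for one exercise.
#'
#' @param ground_truth,predicted [landmark_trajectory()] objects.
#' @param exercise an exercise code (see [exercise_registry()]) or an
#'   `exercise_config`.
#' @param subject_id identifier.
#' @return An object of class `acquisition_pair`.
#' @export
acquisition_pair <- function(ground_truth, predicted, exercise, subject_id = "synthetic") {
  if (!inherits(ground_truth, "landmark_trajectory") ||
      !inherits(predicted, "landmark_trajectory")) {
    stop_romval("ground_truth and predicted must be landmark_trajectory objects",
                "romval_validation_error")
  }
  cfg <- if (inherits(exercise, "exercise_config")) exercise else exercise_config(exercise)
  structure(
    list(ground_truth = ground_truth, predicted = predicted,
         exercise = cfg, subject_id = subject_id),
    class = "acquisition_pair"
  )
}

#' @export
print.acquisition_pair <- function(x, ...) {
  cat("<acquisition_pair>", x$exercise$code, "subject", x$subject_id, "\n")
  cat("  ground truth: "); print(x$ground_truth)
  cat("  predicted:    "); print(x$predicted)
  invisible(x)
}
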