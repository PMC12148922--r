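#' Construct a frame stack
#'
#' The in-memory model of an SWE clip: an ordered list of 8-bit RGB frames
#' sharing one shape, with pixel spacing and B-mode frame rate. All pixel
#' coordinates downstream are row-major, origin top-left, 0-based, with
#' half-open ranges.
#'
#' @param frames List of `h x w x 3` integer arrays.
#' @param pixel_spacing_mm Numeric length-2 `(row, col)` spacing, mm/pixel.
#' @param frame_rate_hz Frame rate; default 11 Hz, the usual B-mode rate.
#' @param source_id Clip identifier (e.g. the file name).
#' @return A `swe_frame_stack` object.
#' @export
frame_stack <- function(frames, pixel_spacing_mm, frame_rate_hz = 11,
                        source_id = "clip") {
  if (length(frames) < 1) stop("a frame stack needs at least one frame")
  d <- dim(frames[[1]])
  if (length(d) != 3 || d[3] != 3) stop("frames must be h x w x 3 arrays")
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must share one shape")
  if (length(pixel_spacing_mm) != 2 || any(pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be two positive lengths (row, col)")
  structure(
    list(frames = frames, pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         frame_rate_hz = frame_rate_hz, source_id = source_id,
         meta = NULL),
    class = "swe_frame_stack")
}

#' @export
print.swe_frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<swe_frame_stack> '%s': %d frames of %d x %d px @ %.3g Hz, %.3g x %.3g mm/px\n",
    x$source_id, length(x$frames), d[1], d[2], x$frame_rate_hz,
    x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  if (!is.null(x$meta))
    cat(sprintf("  meta: %s / %s / %s / %s / rep %d\n", x$meta$participant_id,
                x$meta$muscle, x$meta$task, x$meta$orientation,
                x$meta$repetition))
  invisible(x)
}

#' Read a multiframe SWE clip
#'
#' Reads a DICOM clip into a [frame_stack()]. The frame count comes from the
#' file's NumberOfFrames, pixel spacing from its PixelSpacing attribute, and
#' the frame rate from FrameTime (falling back to 11 Hz, the standard B-mode
#' rate, when the attribute is absent). Frames are returned in acquisition
#' order. Greyscale single-sample files are accepted with the grey channel
#' replicated; a missing or non-positive PixelSpacing raises a calibration
#' error, because all downstream grid geometry is in physical units.
#'
#' @param path Path to a multiframe DICOM file.
#' @return A `swe_frame_stack`.
#' @export
read_swe_clip <- function(path) {
  dcm <- read_dicom_rgb(path)
  if (is.null(dcm$pixel_spacing) || any(dcm$pixel_spacing <= 0))
    stop("calibration error: PixelSpacing (0028,0030) absent or non-positive in ",
         path)
  rate <- if (!is.null(dcm$frame_time_ms) && dcm$frame_time_ms > 0)
    1000 / dcm$frame_time_ms else 11
  frame_stack(dcm$frames, pixel_spacing_mm = dcm$pixel_spacing,
              frame_rate_hz = rate, source_id = basename(path))
}

.MUSCLES <- c("gastrocnemius_medialis", "vastus_lateralis",
              "vastus_medialis", "biceps_femoris")
.TASKS <- c("baseline", "lift_shank", "double_leg_stance",
            "single_leg_stance")
.GROUPS <- c("knee_OA", "old_control", "young_control")
.ORIENTATIONS <- c("longitudinal", "transverse")

#' Recording metadata for one clip
#'
#' Identifies a trial: who was scanned, which muscle (the first or second
#' most painful), under which task and transducer orientation, and which
#' repetition. Baseline is recorded once; the repeated tasks up to three
#' times.
#'
#' @param participant_id Participant identifier.
#' @param group One of `knee_OA`, `old_control`, `young_control`.
#' @param muscle One of `gastrocnemius_medialis`, `vastus_lateralis`,
#'   `vastus_medialis`, `biceps_femoris`.
#' @param task One of `baseline`, `lift_shank`, `double_leg_stance`,
#'   `single_leg_stance`.
#' @param orientation `longitudinal` or `transverse`.
#' @param repetition 1 for baseline; 1-3 for repeated tasks.
#' @param painful_rank Optional 1 (most painful muscle) or 2 (second most).
#' @return A `swe_clip_meta` list.
#' @export
clip_meta <- function(participant_id, group, muscle, task, orientation,
                      repetition = 1L, painful_rank = NULL) {
  if (!nzchar(participant_id)) stop("participant_id must be non-empty")
  if (!group %in% .GROUPS)
    stop("unknown group '", group, "'; allowed: ",
         paste(.GROUPS, collapse = ", "))
  if (!muscle %in% .MUSCLES)
    stop("unknown muscle '", muscle, "'; allowed: ",
         paste(.MUSCLES, collapse = ", "))
  if (!task %in% .TASKS)
    stop("unknown task '", task, "'; allowed: ",
         paste(.TASKS, collapse = ", "))
  if (!orientation %in% .ORIENTATIONS)
    stop("unknown orientation '", orientation, "'; allowed: ",
         paste(.ORIENTATIONS, collapse = ", "))
  repetition <- as.integer(repetition)
  if (task == "baseline" && repetition != 1L)
    stop("baseline is recorded once; repetition must be 1")
  if (task != "baseline" && !repetition %in% 1:3)
    stop("repeated tasks allow repetition 1..3")
  if (!is.null(painful_rank) && !painful_rank %in% 1:2)
    stop("painful_rank must be 1 or 2")
  structure(
    list(participant_id = participant_id, group = group, muscle = muscle,
         task = task, orientation = orientation, repetition = repetition,
         painful_rank = painful_rank),
    class = "swe_clip_meta")
}

#' Attach recording metadata to a frame stack
#'
#' Downstream tables join on
#' `(participant_id, muscle, task, orientation, repetition)`.
#'
#' @param stack A [frame_stack()].
#' @param record A [clip_meta()].
#' @return The stack, with `$meta` set.
#' @export
attach_meta <- function(stack, record) {
  stopifnot(inherits(stack, "swe_frame_stack"),
            inherits(record, "swe_clip_meta"))
  stack$meta <- record
  stack
}
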