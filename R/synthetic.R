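#' Specify a synthetic SWE phantom clip
#'
#' Describes an image-level phantom: a known shear-wave-velocity (SWV) field
#' rendered as a color overlay on synthetic B-mode speckle, written out as a
#' multiframe DICOM clip. The phantom reproduces the acquisition structure of
#' instrumented recordings: greyscale B-mode frames at 11 Hz with an
#' elastogram overlay that updates at its own, slower rate (1.2-2.0 Hz), so
#' consecutive B-mode frames share one elastogram until the next update
#' ("tick"). Elastogram `i` (0-based) covers acquisition times in
#' `[i/elasto_rate, (i+1)/elasto_rate)`.
#'
#' Void pixels (locations without a stiffness estimate, as occur when shear
#' wave tracking fails) are rendered as greyscale; a saturation patch, if
#' requested, is rendered at the top color of the scale and decodes above
#' the 9.9 m/s saturation threshold.
#'
#' @param field_kind `"constant"`, `"linear_gradient"` (left-to-right ramp
#'   from `base_swv` to `lesion_swv`, or `base_swv + 2` if unset), or
#'   `"patch_lesion"` (`base_swv` background with a rectangle at
#'   `lesion_bounds` set to `lesion_swv`).
#' @param base_swv Background SWV in m/s.
#' @param lesion_swv Lesion / gradient-end SWV in m/s (optional).
#' @param lesion_bounds Lesion rectangle in mm relative to the overlay's
#'   top-left corner: `c(row0, row1, col0, col1)`, half-open.
#' @param void_fraction Fraction of overlay pixels rendered void (greyscale),
#'   redrawn at every elastogram tick.
#' @param saturation_fraction Fraction of the overlay area covered by a
#'   fixed saturated patch (values above the saturation threshold).
#' @param duration_s Clip duration in seconds; 20 or 30, the two recording
#'   lengths used in practice.
#' @param bmode_rate_hz B-mode frame rate (fixed 11 Hz).
#' @param elasto_rate_hz Elastogram update rate in \[1.2, 2\] Hz.
#' @param pixel_spacing_mm Pixel spacing (mm/pixel, isotropic).
#' @param noise_sd SD (m/s) of Gaussian noise added to the field
#'   independently at each elastogram tick.
#' @param frame_px `c(rows, cols)` of the full B-mode frame.
#' @param overlay `c(row0, row1, col0, col1)` overlay placement in pixels,
#'   0-based half-open.
#' @param seed Integer RNG seed; the clip is a pure function of the spec.
#' @return A `swe_phantom_spec` list.
#' @export
phantom_spec <- function(field_kind = c("constant", "linear_gradient",
                                        "patch_lesion"),
                         base_swv = 4.2, lesion_swv = NULL,
                         lesion_bounds = NULL,
                         void_fraction = 0.1, saturation_fraction = 0,
                         duration_s = 20, bmode_rate_hz = 11,
                         elasto_rate_hz = 1.6, pixel_spacing_mm = 0.2,
                         noise_sd = 0.05,
                         frame_px = c(120, 180),
                         overlay = c(20, 90, 25, 175),
                         seed = 1L) {
  field_kind <- match.arg(field_kind)
  vmax <- 10
  if (base_swv <= 0 || base_swv >= vmax)
    stop("base_swv must lie in (0, ", vmax, ")")
  if (!is.null(lesion_swv) && (lesion_swv <= 0 || lesion_swv >= vmax))
    stop("lesion_swv must lie in (0, ", vmax, ")")
  if (field_kind == "patch_lesion" &&
      (is.null(lesion_swv) || is.null(lesion_bounds)))
    stop("patch_lesion needs lesion_swv and lesion_bounds")
  if (void_fraction < 0 || saturation_fraction < 0 ||
      void_fraction + saturation_fraction > 1)
    stop("void_fraction + saturation_fraction must lie in [0, 1]")
  if (!duration_s %in% c(20, 30))
    stop("duration_s must be 20 or 30 s")
  if (elasto_rate_hz < 1.2 || elasto_rate_hz > 2.0)
    stop("elasto_rate_hz must lie in [1.2, 2.0]")
  if (duration_s * elasto_rate_hz < 1)
    stop("clip too short to contain a single elastogram")
  if (pixel_spacing_mm <= 0) stop("pixel_spacing_mm must be positive")
  stopifnot(length(frame_px) == 2, length(overlay) == 4,
            overlay[1] >= 0, overlay[2] <= frame_px[1],
            overlay[3] >= 0, overlay[4] <= frame_px[2],
            overlay[2] > overlay[1], overlay[4] > overlay[3])
  structure(
    list(field_kind = field_kind, base_swv = base_swv,
         lesion_swv = lesion_swv, lesion_bounds = lesion_bounds,
         void_fraction = void_fraction,
         saturation_fraction = saturation_fraction,
         duration_s = duration_s, bmode_rate_hz = bmode_rate_hz,
         elasto_rate_hz = elasto_rate_hz,
         pixel_spacing_mm = pixel_spacing_mm, noise_sd = noise_sd,
         frame_px = as.integer(frame_px), overlay = as.integer(overlay),
         seed = as.integer(seed)),
    class = "swe_phantom_spec")
}

#' Generate a phantom SWE clip with exact ground truth
#'
#' Renders the phantom described by `spec` and writes it as a multiframe RGB
#' DICOM clip. The number of B-mode frames is `round(duration_s * 11)`; the
#' overlay updates every `1/elasto_rate_hz` seconds, so the clip embeds
#' `floor(duration_s * elasto_rate_hz)` distinct elastograms (within the
#' half-open tick convention, see [phantom_spec()]).
#'
#' Ground truth is returned alongside the file and is never re-derived from
#' it, so it can serve as an independent oracle for the decoding pipeline.
#' A sidecar CSV (`<out>_frames.csv`, the frame-to-elastogram index map) and
#' a PNG of the first elastogram's validity mask (`<out>_mask.png`) are
#' written next to the clip.
#'
#' @param spec A [phantom_spec()].
#' @param out_path Path of the DICOM file to write.
#' @param scale A [color_scale()]; must be the same scale used for decoding.
#' @param sidecar Write the ground-truth sidecar files? Default `TRUE`.
#' @return Invisibly, a list: `path`; `truth` with `base_field` (noise-free
#'   SWV over the overlay), `fields` (one exact noisy field per elastogram),
#'   `valid_masks`, `saturated_masks`, `frame_elasto_index` (1-based
#'   elastogram index per B-mode frame), `n_elastograms`, `region`
#'   (overlay rectangle, 0-based half-open), and `spec`.
#' @examples
#' \donttest{
#' sc <- color_scale()
#' clip <- make_phantom_clip(phantom_spec(base_swv = 5, seed = 7),
#'                           tempfile(fileext = ".dcm"), sc)
#' clip$truth$n_elastograms
#' }
#' @export
make_phantom_clip <- function(spec, out_path, scale = color_scale(),
                              sidecar = TRUE) {
  stopifnot(inherits(spec, "swe_phantom_spec"))
  dir <- dirname(out_path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)

  h <- spec$overlay[2] - spec$overlay[1]
  w <- spec$overlay[4] - spec$overlay[3]
  sp <- spec$pixel_spacing_mm
  top <- scale$velocities[length(scale$velocities)]

  base <- switch(spec$field_kind,
    constant = matrix(spec$base_swv, h, w),
    linear_gradient = {
      to <- spec$lesion_swv %||% min(spec$base_swv + 2, top)
      matrix(rep(seq(spec$base_swv, to, length.out = w), each = h), h, w)
    },
    patch_lesion = {
      m <- matrix(spec$base_swv, h, w)
      b <- pmin(pmax(round(spec$lesion_bounds / sp), 0), c(h, h, w, w))
      if (b[2] > b[1] && b[4] > b[3])
        m[(b[1] + 1):b[2], (b[3] + 1):b[4]] <- spec$lesion_swv
      m
    })

  n_frames <- round(spec$duration_s * spec$bmode_rate_hz)
  # elastogram index per frame under the half-open tick convention
  idx0 <- floor((seq_len(n_frames) - 1) / spec$bmode_rate_hz *
                  spec$elasto_rate_hz)
  n_el <- max(idx0) + 1L

  sat_mask <- matrix(FALSE, h, w)
  if (spec$saturation_fraction > 0) {
    ph <- round(sqrt(spec$saturation_fraction) * h)
    pw <- round(sqrt(spec$saturation_fraction) * w)
    if (ph > 0 && pw > 0) sat_mask[seq_len(ph), seq_len(pw)] <- TRUE
  }

  withr::with_seed(spec$seed, {
    fields <- valid_masks <- satm <- vector("list", n_el)
    overlays <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      f <- base
      if (spec$noise_sd > 0)
        f <- f + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      f <- pmin(pmax(f, scale$velocities[1]), top)
      f[sat_mask] <- top
      void <- matrix(stats::runif(h * w) < spec$void_fraction, h, w)
      f[void] <- NA_real_
      rgb <- swv_encode(ifelse(is.na(f), 0, f), scale)
      grey <- matrix(sample(20:120, h * w, replace = TRUE), h, w)
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[void] <- grey[void]
        rgb[, , ch] <- plane
      }
      fields[[e]] <- f
      valid_masks[[e]] <- !void
      satm[[e]] <- sat_mask & !void
      overlays[[e]] <- rgb
    }

    frames <- vector("list", n_frames)
    rr <- (spec$overlay[1] + 1):spec$overlay[2]
    cc <- (spec$overlay[3] + 1):spec$overlay[4]
    for (i in seq_len(n_frames)) {
      g <- matrix(sample(20:120, prod(spec$frame_px), replace = TRUE),
                  spec$frame_px[1], spec$frame_px[2])
      fr <- array(c(g, g, g), dim = c(dim(g), 3))
      fr[rr, cc, ] <- overlays[[idx0[i] + 1]]
      storage.mode(fr) <- "integer"
      frames[[i]] <- fr
    }
    write_dicom_rgb(frames, out_path, pixel_spacing = c(sp, sp),
                    frame_rate_hz = spec$bmode_rate_hz)
  })

  if (sidecar) {
    stem <- sub("\\.dcm$", "", out_path)
    utils::write.csv(
      data.frame(frame = seq_len(n_frames), elasto_index = idx0 + 1L),
      paste0(stem, "_frames.csv"), row.names = FALSE)
    png::writePNG(valid_masks[[1]] * 1, paste0(stem, "_mask.png"))
  }

  invisible(list(
    path = out_path,
    truth = list(base_field = base, fields = fields,
                 valid_masks = valid_masks, saturated_masks = satm,
                 frame_elasto_index = idx0 + 1L, n_elastograms = n_el,
                 region = spec$overlay, spec = spec)))
}

#' Group-level median SWV defaults for cohort simulation
#'
#' Reference medians (m/s) per group, muscle, task and transducer
#' orientation used as the default stiffness structure of
#' [simulate_cohort()]: knee-OA, age-matched old-control, and young-control
#' groups; gastrocnemius medialis (GM) and vastus lateralis (VL); four tasks
#' of increasing activation; longitudinal and transverse scanning planes.
#' The structure captures the qualitative pattern of knee-OA cohorts: lower
#' longitudinal stiffness under load and mildly higher transverse stiffness
#' in the OA group.
#'
#' @return A tibble with columns `group`, `muscle`, `task`, `orientation`,
#'   `median_swv`.
#' @export
default_group_medians <- function() {
  tasks <- c("baseline", "lift_shank", "double_leg_stance",
             "single_leg_stance")
  groups <- c("knee_OA", "old_control", "young_control")
  # rows: task within muscle; cols: group
  long_gm <- matrix(c(4.098, 4.254, 4.050,
                      4.114, 4.240, 4.103,
                      4.580, 5.373, 5.264,
                      6.292, 6.803, 7.754), 4, 3, byrow = TRUE)
  long_vl <- matrix(c(4.122, 4.229, 4.040,
                      4.086, 4.162, 4.027,
                      4.192, 4.294, 4.142,
                      4.257, 4.248, 4.112), 4, 3, byrow = TRUE)
  trans_gm <- matrix(c(4.225, 4.048, 4.013,
                       4.164, 4.099, 4.058,
                       4.270, 4.227, 4.142,
                       4.405, 4.390, 4.309), 4, 3, byrow = TRUE)
  trans_vl <- matrix(c(4.235, 4.185, 4.004,
                       4.094, 4.097, 4.030,
                       4.099, 4.230, 4.165,
                       4.093, 4.309, 4.084), 4, 3, byrow = TRUE)
  blocks <- list(
    list(m = "gastrocnemius_medialis", o = "longitudinal", v = long_gm),
    list(m = "vastus_lateralis", o = "longitudinal", v = long_vl),
    list(m = "gastrocnemius_medialis", o = "transverse", v = trans_gm),
    list(m = "vastus_lateralis", o = "transverse", v = trans_vl))
  dplyr::bind_rows(lapply(blocks, function(b) {
    tibble::tibble(
      group = rep(groups, each = 4),
      muscle = b$m,
      task = rep(tasks, times = 3),
      orientation = b$o,
      median_swv = as.vector(b$v))
  }))
}

#' Specify a simulated three-group cohort
#'
#' @param n_per_group Named integer vector of participants per group; names
#'   from `knee_OA`, `old_control`, `young_control`. Default `c(21, 21, 20)`
#'   matching a 62-participant three-group design.
#' @param group_medians Tibble as returned by [default_group_medians()]
#'   giving the population median SWV per (group, muscle, task, orientation).
#' @param between_subject_sd SD (m/s) of the per-participant random offset.
#' @param within_subject_sd SD (m/s) of trial-to-trial noise.
#' @param n_repetitions Repetitions per repeated task (baseline is always
#'   recorded once; all other tasks `n_repetitions` times, default 3).
#' @param muscles Candidate most-painful muscles, assigned to participants
#'   in rotation.
#' @param seed Integer RNG seed.
#' @return A `swe_cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(knee_OA = 21, old_control = 21,
                                        young_control = 20),
                        group_medians = default_group_medians(),
                        between_subject_sd = 0.20,
                        within_subject_sd = 0.10,
                        n_repetitions = 3,
                        muscles = c("gastrocnemius_medialis",
                                    "vastus_lateralis"),
                        seed = 1L) {
  if (length(n_per_group) == 0) stop("empty group list")
  if (is.null(names(n_per_group)))
    stop("n_per_group must be a named vector")
  bad <- setdiff(names(n_per_group),
                 c("knee_OA", "old_control", "young_control"))
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (any(group_medians$median_swv <= 0)) stop("all medians must be > 0")
  if (between_subject_sd < 0 || within_subject_sd < 0)
    stop("SDs must be >= 0")
  structure(
    list(n_per_group = n_per_group, group_medians = group_medians,
         between_subject_sd = between_subject_sd,
         within_subject_sd = within_subject_sd,
         n_repetitions = as.integer(n_repetitions),
         muscles = muscles, seed = as.integer(seed)),
    class = "swe_cohort_spec")
}

#' Simulate trial-level SWV values for a three-group cohort
#'
#' Draws one trial value per participant x task x orientation x repetition as
#' group median + participant offset (`N(0, between_subject_sd)`) +
#' trial noise (`N(0, within_subject_sd)`), truncated below at 0.1 m/s. Each
#' participant is assigned one most-painful muscle (rotating through
#' `spec$muscles`). Baseline is recorded once, every other task
#' `n_repetitions` times, in both scanning planes: with the defaults each
#' participant contributes `2 * (1 + 3 + 3 + 3) = 20` trials and a
#' 21/21/20 cohort yields 1240 rows.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with columns `participant_id`, `group`, `muscle`, `task`,
#'   `orientation`, `repetition`, `true_value` (median + participant offset;
#'   the generator's ground truth) and `swv`. Deterministic for a fixed
#'   `spec$seed`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "swe_cohort_spec"))
  gm <- spec$group_medians
  tasks <- unique(gm$task)
  orientations <- unique(gm$orientation)
  reps_for <- function(task)
    if (task == "baseline") 1L else spec$n_repetitions

  withr::with_seed(spec$seed, {
    rows <- list()
    pid_n <- 0
    for (g in names(spec$n_per_group)) {
      for (i in seq_len(spec$n_per_group[[g]])) {
        pid_n <- pid_n + 1
        pid <- sprintf("P%03d", pid_n)
        muscle <- spec$muscles[(i - 1) %% length(spec$muscles) + 1]
        offset <- stats::rnorm(1, 0, spec$between_subject_sd)
        for (task in tasks) for (orient in orientations) {
          med <- gm$median_swv[gm$group == g & gm$muscle == muscle &
                                 gm$task == task & gm$orientation == orient]
          if (length(med) != 1)
            stop("group_medians must have exactly one row per ",
                 "(group, muscle, task, orientation); missing or duplicated: ",
                 paste(g, muscle, task, orient))
          nr <- reps_for(task)
          noise <- if (spec$within_subject_sd > 0)
            stats::rnorm(nr, 0, spec$within_subject_sd) else rep(0, nr)
          rows[[length(rows) + 1]] <- tibble::tibble(
            participant_id = pid, group = g, muscle = muscle,
            task = task, orientation = orient, repetition = seq_len(nr),
            true_value = pmax(med + offset, 0.1),
            swv = pmax(med + offset + noise, 0.1))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
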