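#' Summarise one clip into a trial-level stiffness value
#'
#' Collapses the per-square, per-elastogram metrics of a clip into one trial
#' value by a two-stage median: per square, the temporal median of the
#' square's `median_swv` over its included frames (QC-discarded frames
#' contribute nothing; neither do square-frames excluded by the colored-
#' pixel rule); then the median over the squares that have at least one
#' included frame. A clip whose frames are all discarded yields
#' `valid = FALSE` with a reason.
#'
#' @param metrics Long tibble of [square_metrics()] rows for every
#'   elastogram of one clip.
#' @param qc Tibble of [apply_qc()] rows, one per elastogram.
#' @param meta Optional [clip_meta()]; its fields are prepended to the
#'   result.
#' @return A one-row tibble: meta columns (if given), `trial_swv`,
#'   `frames_total`, `frames_retained`, `inclusion_pct`, `n_squares_used`,
#'   `valid`, `reason`, plus a `per_square` list-column with the 14
#'   per-square temporal medians.
#' @export
trial_summary <- function(metrics, qc, meta = NULL) {
  if (nrow(metrics) == 0) stop("empty metrics input")
  retained <- qc$elasto_index[!qc$frame_discarded]
  frames_total <- nrow(qc)
  use <- metrics[metrics$elasto_index %in% retained & metrics$included, ]
  per_square <- dplyr::summarise(
    dplyr::group_by(use, .data$square_id),
    square_median = stats::median(.data$median_swv, na.rm = TRUE),
    .groups = "drop")
  defined <- per_square$square_median[!is.na(per_square$square_median)]
  valid <- length(defined) > 0
  out <- tibble::tibble(
    trial_swv = if (valid) stats::median(defined) else NA_real_,
    frames_total = frames_total,
    frames_retained = length(retained),
    inclusion_pct = 100 * length(retained) / frames_total,
    n_squares_used = length(defined),
    valid = valid,
    reason = if (valid) NA_character_ else
      "all frames discarded or no square passed quality control",
    per_square = list(per_square))
  if (!is.null(meta)) {
    out <- dplyr::bind_cols(
      tibble::tibble(
        participant_id = meta$participant_id, group = meta$group,
        muscle = meta$muscle, task = meta$task,
        orientation = meta$orientation, repetition = meta$repetition),
      out)
  }
  out
}

#' Collapse repeated trials of one condition
#'
#' Repeated tasks are recorded up to three times; the condition value is the
#' median across the valid repetitions (robust and consistent with the
#' nonparametric treatment of the stiffness data; the mean is available by
#' argument). Invalid trials (`NA`) are dropped; no valid trial propagates
#' `NA`.
#'
#' @param values Numeric vector of repetition values (may contain `NA`).
#' @param method `"median"` (default) or `"mean"`.
#' @return A single velocity, or `NA` if no repetition is valid.
#' @export
collapse_repetitions <- function(values, method = c("median", "mean")) {
  method <- match.arg(method)
  v <- values[!is.na(values)]
  if (length(v) == 0) return(NA_real_)
  if (method == "median") stats::median(v) else mean(v)
}

#' Longitudinal-to-transverse stiffness ratio
#'
#' Muscle is anisotropic: SWV measured parallel to the fibers (longitudinal)
#' differs from the cross-fiber (transverse) measurement. Their ratio is a
#' two-dimensional indicator of longitudinal tension relative to transverse
#' elasticity; it is scale-free, so a common calibration factor cancels.
#'
#' @param longitudinal,transverse Velocities (m/s), both > 0.
#' @return `longitudinal / transverse`, or `NA` if either is missing.
#' @export
lt_ratio <- function(longitudinal, transverse) {
  ifelse(is.na(longitudinal) | is.na(transverse) |
           longitudinal <= 0 | transverse <= 0,
         NA_real_, longitudinal / transverse)
}

#' Activation ratio: single-leg stance relative to baseline
#'
#' Indicator of stiffness change with high muscle activation: SWV during
#' single-leg stance divided by SWV at rest. Values above 1 indicate
#' stiffening with activity. `direction = "baseline_over_task"` returns the
#' reciprocal.
#'
#' @param single_leg,baseline Velocities (m/s), both > 0.
#' @param direction `"task_over_baseline"` (default) or
#'   `"baseline_over_task"`.
#' @return The ratio, or `NA` if either operand is missing.
#' @export
activation_ratio <- function(single_leg, baseline,
                             direction = c("task_over_baseline",
                                           "baseline_over_task")) {
  direction <- match.arg(direction)
  r <- ifelse(is.na(single_leg) | is.na(baseline) |
                single_leg <= 0 | baseline <= 0,
              NA_real_, single_leg / baseline)
  if (direction == "baseline_over_task") 1 / r else r
}

#' Build the analysis table for a cohort
#'
#' Collapses trial-level values to one row per participant x muscle x task x
#' orientation (median over valid repetitions), attaches both ratio
#' measures, and joins the questionnaire table. Measurements of the first
#' and second most painful muscles are pooled per muscle (the `painful_rank`
#' column, if present, is dropped after pooling). Perceived stiffness is the
#' sum of the two KOOS items that rate stiffness intensity (S6 + S7).
#'
#' Each row carries the longitudinal-to-transverse ratio of its task
#' (defined when both orientations of that task exist) and the single-leg-
#' stance-to-baseline activation ratio of its orientation (defined when both
#' tasks exist).
#'
#' @param trials Tibble of trial-level rows with columns `participant_id`,
#'   `group`, `muscle`, `task`, `orientation`, `repetition`, `swv`
#'   (e.g. from [simulate_cohort()] or stacked [trial_summary()] rows with
#'   `trial_swv` renamed to `swv`).
#' @param questionnaire Optional tibble keyed by `participant_id` with KOOS
#'   subscores (`koos_pain`, `koos_symptoms`, `koos_adl`, `koos_sport`,
#'   `koos_qol`), stiffness items `s6`, `s7`, `tsk`, `age`, `bmi`. Missing
#'   columns are tolerated; missing scores stay `NA`.
#' @param collapse `"median"` (default) or `"mean"`, passed to
#'   [collapse_repetitions()].
#' @return Tibble, one row per participant x muscle x task x orientation,
#'   with `swv`, `lt_ratio`, `activation_ratio`, `perceived_stiffness` and
#'   the questionnaire columns.
#' @export
build_cohort_table <- function(trials, questionnaire = NULL,
                               collapse = "median") {
  keys <- c("participant_id", "group", "muscle", "task", "orientation")
  stopifnot(all(c(keys, "repetition", "swv") %in% names(trials)))
  dup <- dplyr::count(trials, !!!rlang::syms(c(keys, "repetition")))
  dup <- dup[dup$n > 1, ]
  if (nrow(dup) > 0)
    stop("duplicate trial keys: ",
         paste(utils::head(apply(dup[keys], 1, paste, collapse = "/"), 5),
               collapse = "; "))

  cond <- dplyr::summarise(
    dplyr::group_by(trials, !!!rlang::syms(keys)),
    swv = collapse_repetitions(.data$swv, collapse),
    .groups = "drop")

  wide_orient <- tidyr::pivot_wider(
    cond, names_from = "orientation", values_from = "swv")
  if (!"longitudinal" %in% names(wide_orient))
    wide_orient$longitudinal <- NA_real_
  if (!"transverse" %in% names(wide_orient))
    wide_orient$transverse <- NA_real_
  wide_orient$lt_ratio <- lt_ratio(wide_orient$longitudinal,
                                   wide_orient$transverse)
  cond <- dplyr::left_join(
    cond, wide_orient[c("participant_id", "group", "muscle", "task",
                        "lt_ratio")],
    by = c("participant_id", "group", "muscle", "task"))

  wide_task <- tidyr::pivot_wider(
    cond[c(keys, "swv")], names_from = "task", values_from = "swv")
  if (!"single_leg_stance" %in% names(wide_task))
    wide_task$single_leg_stance <- NA_real_
  if (!"baseline" %in% names(wide_task))
    wide_task$baseline <- NA_real_
  wide_task$activation_ratio <- activation_ratio(
    wide_task$single_leg_stance, wide_task$baseline)
  cond <- dplyr::left_join(
    cond, wide_task[c("participant_id", "group", "muscle", "orientation",
                      "activation_ratio")],
    by = c("participant_id", "group", "muscle", "orientation"))

  if (!is.null(questionnaire)) {
    q <- questionnaire
    if (all(c("s6", "s7") %in% names(q)))
      q$perceived_stiffness <- q$s6 + q$s7
    cond <- dplyr::left_join(cond, q, by = "participant_id")
  }
  cond
}
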