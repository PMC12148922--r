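#' Analyse one SWE clip end to end
#'
#' Convenience wrapper chaining the full per-clip pipeline: overlay
#' detection ([detect_overlay_region()]), elastogram deduplication
#' ([dedupe_elastograms()]), color decoding ([decode_elastogram()]), grid
#' construction ([build_grid()]), per-square statistics
#' ([square_metrics()]), frame quality control ([apply_qc()]) and the trial
#' summary ([trial_summary()]).
#'
#' @param clip A file path to a multiframe DICOM clip, or a
#'   [frame_stack()].
#' @param scale A [color_scale()].
#' @param meta Optional [clip_meta()]; if the stack already carries meta
#'   (see [attach_meta()]) that is used.
#' @param anchor Grid anchoring, see [build_grid()].
#' @param unblend Optional overlay un-blending, see [swv_decode_rgb()].
#' @return List: `summary` (the [trial_summary()] row), `metrics` (long
#'   tibble over all elastograms x squares), `qc` (per-elastogram QC),
#'   `region` (overlay rectangle), `n_elastograms`.
#' @export
analyze_clip <- function(clip, scale = color_scale(), meta = NULL,
                         anchor = "topleft", unblend = NULL) {
  stack <- if (is.character(clip)) read_swe_clip(clip) else clip
  stopifnot(inherits(stack, "swe_frame_stack"))
  if (is.null(meta)) meta <- stack$meta

  region <- detect_overlay_region(stack, scale)
  raw <- dedupe_elastograms(stack, region)
  grid <- NULL
  metrics <- vector("list", length(raw$images))
  qc <- vector("list", length(raw$images))
  for (i in seq_along(raw$images)) {
    el <- decode_elastogram(raw$images[[i]], scale,
                            pixel_spacing_mm = stack$pixel_spacing_mm,
                            elasto_index = i, unblend = unblend)
    if (is.null(grid)) grid <- build_grid(el, anchor = anchor)
    metrics[[i]] <- square_metrics(el, grid)
    qc[[i]] <- apply_qc(metrics[[i]])
  }
  metrics <- dplyr::bind_rows(metrics)
  qc <- dplyr::bind_rows(qc)
  list(summary = trial_summary(metrics, qc, meta = meta),
       metrics = metrics, qc = qc, region = region,
       n_elastograms = nrow(qc))
}
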