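#' Rectangle helper (0-based, half-open)
#'
#' All pixel rectangles in the package are `c(row0, row1, col0, col1)`,
#' 0-based with half-open ranges: rows `row0 <= r < row1`. `swe_rect()`
#' validates and tags such a vector.
#'
#' @param row0,row1,col0,col1 Bounds.
#' @return Integer vector of class `swe_rect`.
#' @export
swe_rect <- function(row0, row1, col0, col1) {
  r <- as.integer(c(row0, row1, col0, col1))
  if (r[2] <= r[1] || r[4] <= r[3]) stop("empty rectangle")
  if (r[1] < 0 || r[3] < 0) stop("negative rectangle bounds")
  structure(r, class = "swe_rect", names = c("row0", "row1", "col0", "col1"))
}

.crop <- function(frame, rect) {
  frame[(rect[1] + 1):rect[2], (rect[3] + 1):rect[4], , drop = FALSE]
}

#' Detect the elastogram overlay region within a clip
#'
#' The elastogram overlay is the only colored content in an SWE clip; the
#' B-mode background is greyscale. The detector marks every pixel whose
#' chroma exceeds the scale's `chroma_threshold` in at least one frame,
#' takes connected components of that union mask, and returns the bounding
#' box of the largest component (stray colored annotations elsewhere on
#' screen form smaller components). The transducer is fixed during a
#' recording, so one region serves the whole clip.
#'
#' @param stack A [frame_stack()].
#' @param scale A [color_scale()] (only `chroma_threshold` is used).
#' @return A [swe_rect()], 0-based half-open frame coordinates.
#' @export
detect_overlay_region <- function(stack, scale = color_scale()) {
  stopifnot(inherits(stack, "swe_frame_stack"))
  d <- dim(stack$frames[[1]])
  any_col <- matrix(FALSE, d[1], d[2])
  for (f in stack$frames) {
    any_col <- any_col | (chroma(f) > scale$chroma_threshold)
  }
  if (!any(any_col)) stop("no elastogram found: no colored pixel in any frame")
  lab <- EBImage::bwlabel(any_col * 1)
  areas <- tabulate(lab[lab > 0])
  best <- which.max(areas)
  px <- which(lab == best, arr.ind = TRUE)
  swe_rect(min(px[, 1]) - 1L, max(px[, 1]), min(px[, 2]) - 1L, max(px[, 2]))
}

#' Collapse repeated frames into distinct elastograms
#'
#' The B-mode stream runs at ~11 Hz but the elastogram updates at only
#' 1.2-2.0 Hz, so each elastogram is repeated over several consecutive
#' B-mode frames. Consecutive frames whose overlay-region pixels are
#' bit-identical are collapsed to one raw elastogram image.
#'
#' @param stack A [frame_stack()].
#' @param region A [swe_rect()] from [detect_overlay_region()].
#' @return List with `images` (list of `h x w x 3` overlay crops, in order)
#'   and `first_frame` (1-based B-mode frame index where each first
#'   appears).
#' @export
dedupe_elastograms <- function(stack, region) {
  stopifnot(inherits(stack, "swe_frame_stack"))
  d <- dim(stack$frames[[1]])
  if (region[2] > d[1] || region[4] > d[2])
    stop("region exceeds frame bounds")
  images <- list()
  first_frame <- integer()
  prev <- NULL
  for (i in seq_along(stack$frames)) {
    cur <- .crop(stack$frames[[i]], region)
    if (is.null(prev) || !identical(cur, prev)) {
      images[[length(images) + 1]] <- cur
      first_frame <- c(first_frame, i)
      prev <- cur
    }
  }
  list(images = images, first_frame = first_frame)
}

#' Decode a raw elastogram image to shear wave velocity
#'
#' Applies the inverse color lookup of [swv_decode_rgb()] and packages the
#' result with its geometry: a per-pixel SWV field, a validity mask (colored
#' pixels carrying stiffness information), and a saturation mask (decoded
#' velocity above the scale's saturation threshold, i.e. beyond the
#' instrument's reliable range).
#'
#' @param image `h x w x 3` RGB crop of the overlay region.
#' @param scale A [color_scale()].
#' @param pixel_spacing_mm `(row, col)` spacing, mm/pixel.
#' @param elasto_index 1-based index of this elastogram within its clip.
#' @param unblend Passed to [swv_decode_rgb()].
#' @return A `swe_elastogram` object: `swv` (matrix, `NA` where invalid),
#'   `valid`, `saturated`, `pixel_spacing_mm`, `elasto_index`.
#' @export
decode_elastogram <- function(image, scale = color_scale(),
                              pixel_spacing_mm = c(0.2, 0.2),
                              elasto_index = 1L, unblend = NULL) {
  if (length(image) == 0) stop("empty image")
  dec <- swv_decode_rgb(image, scale, unblend = unblend)
  structure(
    list(swv = dec$swv, valid = dec$valid, saturated = dec$saturated,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         elasto_index = as.integer(elasto_index)),
    class = "swe_elastogram")
}

#' @export
print.swe_elastogram <- function(x, ...) {
  cat(sprintf(
    "<swe_elastogram> #%d: %d x %d px, %.1f%% valid, %d saturated px\n",
    x$elasto_index, nrow(x$swv), ncol(x$swv), 100 * mean(x$valid),
    sum(x$saturated)))
  invisible(x)
}

#' Write a greyscale diagnostic PNG of a decoded elastogram
#'
#' Renders the decoded SWV field as greyscale (scaled over the color
#' scale's range), with invalid pixels black, for visual inspection.
#'
#' @param frame A `swe_elastogram`.
#' @param path Output PNG path.
#' @param scale The [color_scale()] used for decoding (for the range).
#' @return `path`, invisibly.
#' @export
elastogram_diagnostic_png <- function(frame, path, scale = color_scale()) {
  img <- frame$swv / scale$vmax
  img[is.na(img)] <- 0
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
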