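#' Velocity-to-color lookup table for SWE overlays
#'
#' An SWE elastogram encodes shear wave velocity (SWV) as color on top of the
#' greyscale B-mode image. Decoding a clip therefore needs the inverse of the
#' device's color lookup table (LUT). Vendors do not publish their LUTs, so
#' `color_scale()` builds a configurable one: an ordered table of
#' (velocity, RGB) control points along a perceptually ordered blue-to-red
#' path, spanning the device's measurement range. The same table is used to
#' render synthetic phantom clips and to decode them, which makes the
#' encode/decode round trip exact by construction; for real instrument data
#' the `control_points` argument accepts a LUT calibrated from the on-screen
#' color bar.
#'
#' The default table has 200 control points at 0.05 m/s spacing over
#' \[0, 9.95\] m/s, matching a device measurement range of <10 m/s. Pixels
#' decoding above `saturation_threshold` (default 9.9 m/s) are flagged as
#' saturated, i.e. beyond the reliable range. Colored pixels are separated
#' from greyscale (no-information) pixels by chroma, measured as
#' `max(R,G,B) - min(R,G,B)`; a void pixel rendered as pure grey has chroma 0.
#'
#' @param n_points Number of control points (>= 2; default 200).
#' @param vmin,vmax Velocity range covered by the scale in m/s. Control
#'   points span `[vmin, vmax)`; the top control point sits half a
#'   quantization step below `vmax`.
#' @param saturation_threshold Velocity (m/s) above which a decoded pixel is
#'   flagged saturated. Must be below the top control point's velocity.
#' @param chroma_threshold Color distance (0-255 units) strictly above which
#'   a pixel counts as colored. Default 8.
#' @param control_points Optional replacement LUT: a data frame with columns
#'   `velocity`, `r`, `g`, `b` (velocities strictly increasing, channels in
#'   0-255). Overrides `n_points`/`vmin`/`vmax` for the color path.
#'
#' @return An object of class `swe_color_scale`: a list with `velocities`
#'   (numeric), `colors` (n x 3 integer matrix), `vmin`, `vmax`,
#'   `saturation_threshold`, `chroma_threshold`, and `step` (the LUT
#'   quantization step in m/s).
#'
#' @examples
#' sc <- color_scale()
#' rgb <- swv_encode(matrix(5, 2, 2), sc)
#' swv_decode_rgb(rgb, sc)$swv
#' @export
color_scale <- function(n_points = 200, vmin = 0, vmax = 10,
                        saturation_threshold = 9.9, chroma_threshold = 8,
                        control_points = NULL) {
  if (is.null(control_points)) {
    if (n_points < 2) stop("a color scale needs at least 2 control points")
    step <- (vmax - vmin) / n_points
    v <- vmin + (seq_len(n_points) - 1) * step
    cols <- .jet_path((v - vmin) / (vmax - vmin - step))
  } else {
    stopifnot(all(c("velocity", "r", "g", "b") %in% names(control_points)))
    v <- control_points$velocity
    if (any(diff(v) <= 0)) stop("control point velocities must be strictly increasing")
    cols <- cbind(control_points$r, control_points$g, control_points$b)
    step <- if (length(v) > 1) stats::median(diff(v)) else vmax - vmin
    vmin <- v[1]
  }
  if (saturation_threshold >= vmax)
    stop("saturation_threshold must lie below vmax")
  structure(
    list(velocities = v,
         colors = cols,
         vmin = vmin, vmax = vmax,
         saturation_threshold = saturation_threshold,
         chroma_threshold = chroma_threshold,
         step = step),
    class = "swe_color_scale")
}

# blue -> cyan -> green -> yellow -> red, t in [0, 1]
.jet_path <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  anchors <- matrix(c(
    0,   0,   255,
    0,   255, 255,
    0,   255, 0,
    255, 255, 0,
    255, 0,   0), ncol = 3, byrow = TRUE)
  pos <- seq(0, 1, length.out = nrow(anchors))
  cols <- vapply(1:3, function(ch)
    stats::approx(pos, anchors[, ch], xout = t, rule = 2)$y, numeric(length(t)))
  matrix(as.integer(round(cols)), ncol = 3)
}

#' @export
print.swe_color_scale <- function(x, ...) {
  cat(sprintf(
    "<swe_color_scale> %d control points over [%g, %g) m/s (step %.3g m/s)\n",
    length(x$velocities), x$vmin, x$vmax, x$step))
  cat(sprintf("  saturation > %g m/s, chroma threshold %g\n",
              x$saturation_threshold, x$chroma_threshold))
  invisible(x)
}

#' Chroma of RGB pixels
#'
#' Chroma is measured as `max(R,G,B) - min(R,G,B)` per pixel. Greyscale
#' pixels (R=G=B) have chroma 0; overlay colors on the default scale have
#' chroma 255. Pixels are colored when chroma strictly exceeds the scale's
#' `chroma_threshold`.
#'
#' @param rgb An `h x w x 3` numeric array, or an `n x 3` matrix of pixels.
#' @return Matrix (or vector) of chroma values in 0-255.
#' @export
chroma <- function(rgb) {
  if (length(dim(rgb)) == 3) {
    pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3]) -
      pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  } else {
    apply(rgb, 1, max) - apply(rgb, 1, min)
  }
}

#' Encode a velocity field as overlay colors
#'
#' Maps velocities to RGB by piecewise-linear interpolation along the scale's
#' control-point path, with 8-bit rounding. Values outside the table are
#' clamped to its ends.
#'
#' @param field Numeric matrix of velocities (m/s).
#' @param scale A [color_scale()].
#' @return An `nrow x ncol x 3` integer array of RGB values in 0-255.
#' @export
swv_encode <- function(field, scale) {
  v <- as.vector(field)
  out <- array(0L, dim = c(nrow(field), ncol(field), 3))
  for (ch in 1:3) {
    y <- stats::approx(scale$velocities, scale$colors[, ch], xout = v,
                       rule = 2)$y
    out[, , ch] <- as.integer(round(pmin(pmax(y, 0), 255)))
  }
  out
}

#' Decode overlay colors back to velocity
#'
#' Inverse of [swv_encode()]: each colored pixel is matched to its nearest
#' LUT control point (Euclidean distance in RGB), then refined by projecting
#' onto the line segments to the neighboring control points and
#' piecewise-linearly interpolating the velocity. Pixels whose chroma does
#' not exceed the scale's `chroma_threshold` are grey (no stiffness
#' information) and decode to `NA`.
#'
#' @param rgb `h x w x 3` array of 8-bit RGB values.
#' @param scale A [color_scale()].
#' @param unblend Optional list `list(alpha=, background=)`: if the overlay
#'   was alpha-blended onto a known background, invert the blend
#'   (`(pixel - (1-alpha)*background) / alpha`) before lookup. `background`
#'   is a single grey level or an RGB triple. Default `NULL` (the LUT is
#'   taken to represent the on-screen, already-blended colors).
#' @return List with `swv` (matrix, `NA` where invalid), `valid` and
#'   `saturated` logical matrices.
#' @export
swv_decode_rgb <- function(rgb, scale, unblend = NULL) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  px <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
              as.vector(rgb[, , 3]))
  valid <- (apply(px, 1, max) - apply(px, 1, min)) > scale$chroma_threshold
  swv <- rep(NA_real_, h * w)
  if (any(valid)) {
    p <- px[valid, , drop = FALSE]
    if (!is.null(unblend)) {
      bg <- rep(unblend$background, length.out = 3)
      p <- sweep(p, 2, (1 - unblend$alpha) * bg) / unblend$alpha
    }
    swv[valid] <- .decode_pixels(p, scale)
  }
  swv <- matrix(swv, h, w)
  valid <- matrix(valid, h, w)
  list(swv = swv, valid = valid,
       saturated = valid & !is.na(swv) & swv > scale$saturation_threshold)
}

# nearest control point + projection onto adjacent LUT segments
.decode_pixels <- function(p, scale) {
  cp <- scale$colors
  n <- nrow(cp)
  d2 <- outer(rowSums(p^2), rep(1, n)) +
    outer(rep(1, nrow(p)), rowSums(cp^2)) - 2 * p %*% t(cp)
  j <- max.col(-d2, ties.method = "first")

  proj <- function(j0, j1) {
    # returns cbind(velocity, squared residual) for projection onto segment
    u <- cp[j1, , drop = FALSE] - cp[j0, , drop = FALSE]
    uu <- rowSums(u^2)
    t <- rowSums((p - cp[j0, , drop = FALSE]) * u) / pmax(uu, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    foot <- cp[j0, , drop = FALSE] + u * t
    v <- scale$velocities[j0] + t * (scale$velocities[j1] - scale$velocities[j0])
    cbind(v, rowSums((p - foot)^2))
  }
  left <- proj(pmax(j - 1, 1), j)
  right <- proj(j, pmin(j + 1, n))
  ifelse(left[, 2] <= right[, 2], left[, 1], right[, 1])
}
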