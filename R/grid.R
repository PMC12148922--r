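#' Build the 2x7 analysis grid over a decoded elastogram
#'
#' The top 1 mm of the elastogram is discarded (edge artifacts at the
#' overlay border), and the remainder is tiled with 14 squares of
#' 4 mm x 4 mm: row A (top, A1..A7 left to right) and row B below it
#' (B1..B7). In pixels, the discarded strip is `ceiling(1 / row_spacing)`
#' rows - never keeping any of the discarded millimetre - and the square
#' side is `round(4 / spacing)` pixels per axis. Squares are anchored at the
#' top-left of the retained region by default; leftover right/bottom margins
#' are unused.
#'
#' @param frame A `swe_elastogram` (only its geometry is used).
#' @param square_mm Square side in mm (default 4).
#' @param discard_top_mm Discarded top strip in mm (default 1).
#' @param anchor `"topleft"` (default) or `"center"`, centring the 2x7
#'   block within the retained region.
#' @return A `swe_grid`: tibble of 14 rows with `square_id` (A1..B7) and
#'   0-based half-open pixel bounds `row0, row1, col0, col1` relative to
#'   the elastogram region, plus attributes `discard_px` and `side_px`.
#' @export
build_grid <- function(frame, square_mm = 4, discard_top_mm = 1,
                       anchor = c("topleft", "center")) {
  stopifnot(inherits(frame, "swe_elastogram"))
  anchor <- match.arg(anchor)
  sp <- frame$pixel_spacing_mm
  h <- nrow(frame$swv); w <- ncol(frame$swv)
  discard <- ceiling(discard_top_mm / sp[1])
  side_r <- round(square_mm / sp[1])
  side_c <- round(square_mm / sp[2])
  need_h <- discard + 2 * side_r
  need_w <- 7 * side_c
  if (h < need_h || w < need_w)
    stop(sprintf(
      paste0("overlay region too small for the 2x7 grid: have ",
             "%.1f x %.1f mm, need %.1f x %.1f mm ",
             "(1 mm top discard + 2x7 squares of %g mm)"),
      h * sp[1], w * sp[2], need_h * sp[1], need_w * sp[2], square_mm))
  r_off <- discard
  c_off <- 0L
  if (anchor == "center") {
    r_off <- discard + floor((h - need_h) / 2)
    c_off <- floor((w - need_w) / 2)
  }
  rows <- lapply(seq_len(14), function(k) {
    band <- (k - 1) %/% 7    # 0 = A, 1 = B
    col <- (k - 1) %% 7
    tibble::tibble(
      square_id = paste0(c("A", "B")[band + 1], col + 1),
      row0 = r_off + band * side_r, row1 = r_off + (band + 1) * side_r,
      col0 = c_off + col * side_c, col1 = c_off + (col + 1) * side_c)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "discard_px") <- discard
  attr(out, "side_px") <- c(side_r, side_c)
  class(out) <- c("swe_grid", class(out))
  out
}

#' Per-square statistics for one elastogram
#'
#' For each of the 14 grid squares, computes over the square's valid
#' (colored) pixels: maximum, mean and median SWV, standard deviation and
#' interquartile range, the percentage of colored pixels, and the count and
#' percentage of saturated pixels (decoded SWV above the scale's saturation
#' threshold, default > 9.9 m/s). Quantiles use the linear-interpolation
#' convention between order statistics ([stats::quantile()] type 7).
#' Saturated pixels stay in the statistics - saturation is reported, not
#' filtered. A square with no valid pixel gets `NA` statistics and
#' `colored_pct = 0`. A square is `included` when at least 50% of its
#' pixels are colored (strictly less than 50% excludes it).
#'
#' @param frame A `swe_elastogram`.
#' @param grid A [build_grid()] result for this frame's geometry.
#' @param colored_cutoff_pct Inclusion cutoff on `colored_pct`; default 50.
#' @return Tibble of 14 rows: `square_id`, `elasto_index`, `max_swv`,
#'   `mean_swv`, `median_swv`, `sd_swv`, `iqr_swv`, `colored_pct`,
#'   `saturated_n`, `saturated_pct`, `included`.
#' @export
square_metrics <- function(frame, grid, colored_cutoff_pct = 50) {
  stopifnot(inherits(frame, "swe_elastogram"), inherits(grid, "swe_grid"))
  res <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    rr <- (g$row0 + 1):g$row1
    cc <- (g$col0 + 1):g$col1
    valid <- frame$valid[rr, cc]
    vals <- frame$swv[rr, cc][valid]
    n_px <- length(valid)
    n_sat <- sum(frame$saturated[rr, cc])
    colored_pct <- 100 * sum(valid) / n_px
    if (length(vals) == 0) {
      stats_row <- list(max_swv = NA_real_, mean_swv = NA_real_,
                        median_swv = NA_real_, sd_swv = NA_real_,
                        iqr_swv = NA_real_)
    } else {
      stats_row <- list(
        max_swv = max(vals), mean_swv = mean(vals),
        median_swv = stats::median(vals),
        sd_swv = if (length(vals) > 1) stats::sd(vals) else 0,
        iqr_swv = stats::IQR(vals, type = 7))
    }
    tibble::tibble(
      square_id = g$square_id, elasto_index = frame$elasto_index,
      !!!stats_row,
      colored_pct = colored_pct, saturated_n = n_sat,
      saturated_pct = 100 * n_sat / n_px,
      included = colored_pct >= colored_cutoff_pct)
  })
  dplyr::bind_rows(res)
}

#' Frame-level quality control
#'
#' A square-frame is excluded when fewer than 50% of its pixels are colored
#' (strict: exactly 50% is retained). The whole elastogram is discarded when
#' more than 50% of its 14 squares are excluded - strictly more, so 7 of 14
#' retains the frame and 8 discards it.
#'
#' @param metrics The 14-row tibble from [square_metrics()].
#' @return A one-row tibble: `elasto_index`, `n_squares_excluded`,
#'   `frame_discarded`.
#' @export
apply_qc <- function(metrics) {
  if (nrow(metrics) != 14)
    stop("expected exactly 14 square rows, got ", nrow(metrics))
  n_exc <- sum(!metrics$included)
  tibble::tibble(
    elasto_index = metrics$elasto_index[1],
    n_squares_excluded = n_exc,
    frame_discarded = n_exc > nrow(metrics) / 2)
}
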