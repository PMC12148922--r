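# Programmatic fixtures; expensive phantom clips are generated once per test
# run and shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

# 30 s @ 1.6 Hz phantom (48 embedded elastograms), constant 5 m/s field
shared_phantom_30s <- function() {
  if (is.null(.fixture_cache$p30)) {
    path <- file.path(tempdir(), "phantom30.dcm")
    spec <- phantom_spec(base_swv = 5, void_fraction = 0.1,
                         duration_s = 30, elasto_rate_hz = 1.6,
                         noise_sd = 0.05, seed = 11L)
    .fixture_cache$p30 <- list(clip = make_phantom_clip(spec, path),
                               path = path, spec = spec)
  }
  .fixture_cache$p30
}

# 20 s @ 1.2 Hz noise-free phantom with voids (round-trip / mask oracle)
shared_phantom_clean <- function() {
  if (is.null(.fixture_cache$pclean)) {
    path <- file.path(tempdir(), "phantom_clean.dcm")
    spec <- phantom_spec(base_swv = 4.2, void_fraction = 0.2,
                         duration_s = 20, elasto_rate_hz = 1.2,
                         noise_sd = 0, seed = 12L)
    .fixture_cache$pclean <- list(clip = make_phantom_clip(spec, path),
                                  path = path, spec = spec)
  }
  .fixture_cache$pclean
}

# grey frame with an optional colored rectangle (0-based half-open bounds)
grey_frame <- function(h, w, grey = 60L) {
  array(as.integer(grey), dim = c(h, w, 3))
}

paint_rect <- function(frame, rect, rgb = c(255L, 0L, 0L)) {
  for (ch in 1:3) {
    frame[(rect[1] + 1):rect[2], (rect[3] + 1):rect[4], ch] <- rgb[ch]
  }
  frame
}

# a decoded elastogram built directly from a velocity field (NA = void),
# bypassing the color pathway; for grid/aggregation geometry tests
fake_elastogram <- function(swv, spacing = c(0.1, 0.1), index = 1L,
                            sat_threshold = 9.9) {
  valid <- !is.na(swv)
  structure(
    list(swv = swv, valid = valid,
         saturated = valid & !is.na(swv) & swv > sat_threshold,
         pixel_spacing_mm = spacing, elasto_index = as.integer(index)),
    class = "swe_elastogram")
}

# 14-square metrics table with given per-square colored percentages and
# median values; for QC and trial-summary tests
fake_metrics <- function(colored_pct, medians = rep(5, 14), index = 1L) {
  stopifnot(length(colored_pct) == 14)
  tibble::tibble(
    square_id = paste0(rep(c("A", "B"), each = 7), rep(1:7, 2)),
    elasto_index = as.integer(index),
    max_swv = medians, mean_swv = medians, median_swv = medians,
    sd_swv = 0, iqr_swv = 0,
    colored_pct = colored_pct,
    saturated_n = 0L, saturated_pct = 0,
    included = colored_pct >= 50)
}
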