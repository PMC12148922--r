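#' @title Minimal multiframe RGB DICOM i/o
#' @description
#' SWE clips are exported by the instrument as multiframe DICOM files with
#' interleaved 8-bit RGB pixel data. These helpers write and read exactly
#' that profile: explicit VR little endian transfer syntax, Secondary
#' Capture Multiframe True Color SOP class, one contiguous uncompressed
#' PixelData element. They are not a general DICOM implementation (no
#' sequences, no compressed transfer syntaxes, no implicit VR).
#' @name dicom_io
#' @keywords internal
NULL

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_MF_TRUE_COLOR <- "1.2.840.10008.5.1.4.1.1.7.4"
.IMPL_UID <- "1.2.826.0.1.3680043.10.1521.1"

.uid_new <- function() {
  # derived from time + RNG-independent counter; uniqueness per session is enough
  paste0(.IMPL_UID, ".", format(as.integer(Sys.time()) %% 1e9),
         ".", sample.int(1e6, 1))
}

.el_short <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    value_raw <- c(value_raw, as.raw(if (vr == "UI") 0 else 0x20))
  c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
    charToRaw(vr),
    writeBin(length(value_raw), raw(), size = 2, endian = "little"),
    value_raw)
}

.el_long <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
    charToRaw(vr), as.raw(c(0, 0)),
    writeBin(length(value_raw), raw(), size = 4, endian = "little"),
    value_raw)
}

.el_str <- function(group, elem, vr, s) .el_short(group, elem, vr, charToRaw(s))
.el_us <- function(group, elem, x)
  .el_short(group, elem, "US", writeBin(as.integer(x), raw(), size = 2,
                                        endian = "little"))

#' Write a multiframe RGB DICOM file
#'
#' @param frames List of `h x w x 3` integer arrays (values 0-255), one per
#'   frame, all the same shape.
#' @param path Output file path.
#' @param pixel_spacing Numeric length-2 `(row, col)` spacing in mm/pixel,
#'   or `NULL` to omit the PixelSpacing attribute (used to exercise
#'   calibration-error handling downstream).
#' @param frame_rate_hz Acquisition frame rate; stored as FrameTime (ms) and
#'   CineRate.
#' @return `path`, invisibly.
#' @keywords internal
#' @export
write_dicom_rgb <- function(frames, path, pixel_spacing = c(0.2, 0.2),
                            frame_rate_hz = 11) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  if (length(d) != 3 || d[3] != 3)
    stop("frames must be h x w x 3 arrays")
  sop_uid <- .uid_new()

  meta <- c(
    .el_long(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    .el_str(0x0002L, 0x0002L, "UI", .SOP_MF_TRUE_COLOR),
    .el_str(0x0002L, 0x0003L, "UI", sop_uid),
    .el_str(0x0002L, 0x0010L, "UI", .TS_EXPLICIT_LE),
    .el_str(0x0002L, 0x0012L, "UI", .IMPL_UID))
  meta <- c(.el_short(0x0002L, 0x0000L, "UL",
                      writeBin(length(meta), raw(), size = 4,
                               endian = "little")),
            meta)

  body <- c(
    .el_str(0x0008L, 0x0016L, "UI", .SOP_MF_TRUE_COLOR),
    .el_str(0x0008L, 0x0018L, "UI", sop_uid),
    .el_str(0x0008L, 0x0060L, "CS", "US"),
    .el_str(0x0018L, 0x0040L, "IS", as.character(round(frame_rate_hz))),
    .el_str(0x0018L, 0x1063L, "DS", sprintf("%.6f", 1000 / frame_rate_hz)),
    .el_str(0x0020L, 0x000DL, "UI", .uid_new()),
    .el_str(0x0020L, 0x000EL, "UI", .uid_new()),
    .el_us(0x0028L, 0x0002L, 3),
    .el_str(0x0028L, 0x0004L, "CS", "RGB"),
    .el_us(0x0028L, 0x0006L, 0),
    .el_str(0x0028L, 0x0008L, "IS", as.character(length(frames))),
    .el_us(0x0028L, 0x0010L, d[1]),
    .el_us(0x0028L, 0x0011L, d[2]))
  if (!is.null(pixel_spacing))
    body <- c(body, .el_str(0x0028L, 0x0030L, "DS",
                            sprintf("%.6f\\%.6f", pixel_spacing[1],
                                    pixel_spacing[2])))
  body <- c(body,
            .el_us(0x0028L, 0x0100L, 8), .el_us(0x0028L, 0x0101L, 8),
            .el_us(0x0028L, 0x0102L, 7), .el_us(0x0028L, 0x0103L, 0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)

  total <- as.integer(prod(d)) * length(frames)
  npx <- if (total %% 2 == 1) total + 1L else total
  writeBin(c(writeBin(c(0x7FE0L, 0x0010L), raw(), size = 2,
                      endian = "little"),
             charToRaw("OB"), as.raw(c(0, 0)),
             writeBin(as.integer(npx), raw(), size = 4,
                      endian = "little")), con)
  for (f in frames) {
    # interleaved RGB, row-major: channel fastest, then column, then row
    writeBin(as.raw(as.vector(aperm(f, c(3, 2, 1)))), con)
  }
  if (total %% 2 == 1) writeBin(raw(1), con)
  invisible(path)
}

#' Read a multiframe RGB DICOM file
#'
#' Parses an explicit-VR little-endian DICOM file and returns its attributes
#' and pixel frames. Greyscale single-sample files are accepted with the
#' grey channel replicated to RGB.
#'
#' @param path File path.
#' @return List with `frames` (list of `h x w x 3` integer arrays),
#'   `pixel_spacing` (mm, or `NULL` if absent), `frame_time_ms` (or `NULL`),
#'   `n_frames`, `rows`, `cols`.
#' @keywords internal
#' @export
read_dicom_rgb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)

  u16 <- function(i) readBin(bytes[i:(i + 1)], integer(), size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(bytes[i:(i + 3)], integer(), size = 4,
                             endian = "little")

  pos <- 133
  attrs <- list()
  pixel_data <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or corrupt element at byte ", pos,
           "; only explicit VR little endian is supported")
    if (vr %in% long_vrs) {
      len <- u32(pos + 8)
      val_at <- pos + 12
    } else {
      len <- u16(pos + 6)
      val_at <- pos + 8
    }
    if (len < 0) stop("undefined-length element not supported")
    val <- if (len > 0) bytes[val_at:(val_at + len - 1)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    if (group == 0x7FE0 && elem == 0x0010) {
      pixel_data <- val
    } else if (vr %in% c("UI", "CS", "IS", "DS", "LO", "SH", "PN", "DA", "TM")) {
      v <- val
      while (length(v) && v[length(v)] %in% as.raw(c(0x00, 0x20)))
        v <- v[-length(v)]
      attrs[[key]] <- rawToChar(v)
    } else if (vr == "US") {
      attrs[[key]] <- u16(val_at)
    }
    pos <- val_at + len
  }

  ts <- attrs[["0002,0010"]]
  if (!is.null(ts) && ts != .TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  if (is.null(pixel_data)) stop("no PixelData element in ", path)

  rows <- attrs[["0028,0010"]]; cols <- attrs[["0028,0011"]]
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns")
  spp <- attrs[["0028,0002"]] %||% 1L
  planar <- attrs[["0028,0006"]] %||% 0L
  nf <- as.integer(attrs[["0028,0008"]] %||% "1")

  frame_px <- rows * cols * spp
  if (length(pixel_data) < frame_px * nf)
    stop("PixelData shorter than Rows*Columns*SamplesPerPixel*NumberOfFrames")
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    v <- as.integer(pixel_data[((i - 1) * frame_px + 1):(i * frame_px)])
    if (spp == 3) {
      a <- if (planar == 0) {
        aperm(array(v, dim = c(3, cols, rows)), c(3, 2, 1))
      } else {
        aperm(array(v, dim = c(cols, rows, 3)), c(2, 1, 3))
      }
    } else {
      m <- t(matrix(v, nrow = cols))
      a <- array(c(m, m, m), dim = c(rows, cols, 3))
    }
    storage.mode(a) <- "integer"
    frames[[i]] <- a
  }

  spacing <- NULL
  if (!is.null(attrs[["0028,0030"]])) {
    spacing <- as.numeric(strsplit(attrs[["0028,0030"]], "\\\\")[[1]])
  }
  ft <- if (!is.null(attrs[["0018,1063"]])) as.numeric(attrs[["0018,1063"]])
  list(frames = frames, pixel_spacing = spacing, frame_time_ms = ft,
       n_frames = nf, rows = rows, cols = cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
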