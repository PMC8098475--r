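# Minimal MRC2014 raster I/O.
#
# Only what the workflow needs: single 2-D images, modes 0 (int8),
# 1 (int16), 2 (float32) and 6 (uint16), little-endian, pixel size from
# the cell dimensions.  The extended header is skipped.  Exposure time,
# which MRC has no standard slot for, is carried in a text label of the
# form "icethick exposure_s=<t>" and recovered on read.

MRC_HEADER_BYTES <- 1024L

#' Read a 2-D MRC image
#'
#' Reads a single-section MRC2014 file (modes 0, 1, 2 or 6) into an
#' [image_plane()].  The pixel size comes from the `cella`/`mx` header
#' fields; an exposure time stored in a header label by [write_image()]
#' is recovered, otherwise it defaults to 1 s with a warning.
#'
#' @param path Path to the MRC file.
#' @param slit_inserted Logical carried into the returned plane (whether
#'   the energy-filter slit was inserted for this image).
#' @return An [image_plane()].
#' @export
read_image <- function(path, slit_inserted = FALSE) {
  if (!file.exists(path)) {
    ice_stop("format_error", "MRC file not found: %s", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  head_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- head_int[1L]; ny <- head_int[2L]; nz <- head_int[3L]
  mode <- head_int[4L]
  mx <- head_int[8L]
  seek(con, 40L)
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, 220L)
  nlabl <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  labels <- character(0)
  if (nlabl > 0 && nlabl <= 10) {
    seek(con, 224L)
    for (i in seq_len(nlabl)) {
      raw <- readBin(con, "raw", n = 80L)
      labels <- c(labels, trimws(rawToChar(raw[raw != as.raw(0)])))
    }
  }
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 65536 || ny > 65536) {
    ice_stop("format_error", "implausible MRC dimensions %dx%dx%d (field nx/ny/nz)",
             nx, ny, nz)
  }
  if (nz != 1L) {
    ice_stop("format_error",
             "expected a single 2-D image but nz = %d (field nz): stacks/volumes are not supported",
             nz)
  }
  if (!mode %in% c(0L, 1L, 2L, 6L)) {
    ice_stop("format_error", "unsupported MRC mode %d (field mode)", mode)
  }
  seek(con, MRC_HEADER_BYTES + max(nsymbt, 0L))
  n <- nx * ny
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little")
  )
  if (length(data) != n) {
    ice_stop("format_error", "truncated MRC data block in %s", path)
  }
  # MRC stores x (columns) fastest; our matrices are [row, col].
  m <- t(matrix(as.numeric(data), nrow = nx, ncol = ny))
  pixel_size_a <- if (mx > 0 && cella[1L] > 0) cella[1L] / mx else NA_real_
  if (!is.finite(pixel_size_a) || pixel_size_a <= 0) {
    ice_warn("missing_metadata",
             "no pixel size in MRC header of %s; defaulting to 1 Angstrom/px", path)
    pixel_size_a <- 1
  }
  exposure_s <- NA_real_
  for (lab in labels) {
    hit <- regmatches(lab, regexec("exposure_s=([0-9.eE+-]+)", lab))[[1L]]
    if (length(hit) == 2L) exposure_s <- as.numeric(hit[2L])
  }
  if (!is.finite(exposure_s) || exposure_s <= 0) {
    ice_warn("missing_metadata",
             "no exposure time in MRC header of %s; defaulting to 1 s", path)
    exposure_s <- 1
  }
  image_plane(m, pixel_size_a = pixel_size_a, exposure_s = exposure_s,
              slit_inserted = slit_inserted, label = basename(path))
}

#' Write an image plane as MRC
#'
#' Writes a single 2-D image as little-endian MRC2014, mode 2 (float32)
#' by default.  The pixel size goes into the cell dimensions and the
#' exposure time into a header label so that [read_image()] round-trips
#' the metadata.
#'
#' @param plane An [image_plane()] (or a bare numeric matrix, for which
#'   a pixel size must be given).
#' @param path Output path.
#' @param mode MRC mode: 0, 1, 2 or 6.
#' @param pixel_size_a Pixel size override in Angstrom per pixel.
#' @return `path`, invisibly.
#' @export
write_image <- function(plane, path, mode = 2L, pixel_size_a = NULL) {
  if (is.matrix(plane)) {
    plane <- image_plane(plane, pixel_size_a = pixel_size_a %||% 1,
                         exposure_s = 1)
  }
  stopifnot(inherits(plane, "image_plane"))
  if (!mode %in% c(0L, 1L, 2L, 6L)) {
    ice_stop("format_error", "unsupported MRC mode %d", mode)
  }
  ps <- pixel_size_a %||% plane$pixel_size_a
  m <- plane$data
  nx <- ncol(m); ny <- nrow(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L))                      # nx ny nz
  wi(mode)                               # mode
  wi(c(0L, 0L, 0L))                      # nxstart nystart nzstart
  wi(c(nx, ny, 1L))                      # mx my mz
  wf(c(nx * ps, ny * ps, ps))            # cella
  wf(c(90, 90, 90))                      # cellb
  wi(c(1L, 2L, 3L))                      # mapc mapr maps
  wf(c(min(m), max(m), mean(m)))         # dmin dmax dmean
  wi(c(0L, 0L))                          # ispg nsymbt
  writeBin(raw(100L), con)               # extra (incl. exttyp)
  wf(c(0, 0, 0))                         # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(m))                       # rms
  wi(1L)                                 # nlabl
  lab <- sprintf("icethick exposure_s=%.10g", plane$exposure_s)
  lab_raw <- charToRaw(formatC(lab, width = -80))
  writeBin(lab_raw[seq_len(80L)], con)
  writeBin(raw(80L * 9L), con)           # remaining labels
  stopifnot(seek(con) == MRC_HEADER_BYTES)
  v <- as.vector(t(m))                   # x fastest
  switch(as.character(mode),
    "0" = writeBin(as.integer(round(v)), con, size = 1L, endian = "little"),
    "1" = writeBin(as.integer(round(v)), con, size = 2L, endian = "little"),
    "2" = writeBin(as.numeric(v), con, size = 4L, endian = "little"),
    "6" = {
      iv <- as.integer(round(v))
      if (any(iv < 0L)) {
        ice_stop("format_error", "mode 6 (uint16) cannot store negative values")
      }
      # writeBin has no unsigned 16-bit type; values < 32768 write
      # identically, larger ones wrap to the signed range on purpose.
      iv[iv > 32767L] <- iv[iv > 32767L] - 65536L
      writeBin(iv, con, size = 2L, endian = "little")
    }
  )
  invisible(path)
}
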