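#' Image plane: a 2-D counts image with acquisition metadata
#'
#' The elementary raster object of the workflow: a matrix of per-pixel
#' counts plus pixel size, exposure time, and whether the energy-filter
#' slit was inserted during acquisition (filtered vs unfiltered channel).
#' Pixel coordinates throughout the package are 1-based `(row, col)` with
#' row 1 at the top, matching R matrix indexing.
#'
#' @param data Numeric matrix of per-pixel counts, at least 16 x 16.
#' @param pixel_size_a Physical pixel size in Angstrom per pixel.
#' @param exposure_s Exposure time in seconds.
#' @param slit_inserted `TRUE` for the zero-loss filtered image.
#' @param label Free text.
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(data, pixel_size_a, exposure_s = 1,
                        slit_inserted = FALSE, label = "") {
  if (!is.matrix(data) || !is.numeric(data)) {
    ice_stop("domain_error", "data must be a numeric matrix")
  }
  if (nrow(data) < 16L || ncol(data) < 16L) {
    ice_stop("domain_error", "image must be at least 16 x 16 pixels, got %d x %d",
             nrow(data), ncol(data))
  }
  if (!is_number(pixel_size_a) || pixel_size_a <= 0) {
    ice_stop("domain_error", "pixel_size_a must be > 0")
  }
  if (!is_number(exposure_s) || exposure_s <= 0) {
    ice_stop("domain_error", "exposure_s must be > 0")
  }
  structure(
    list(data = data, pixel_size_a = as.numeric(pixel_size_a),
         exposure_s = as.numeric(exposure_s),
         slit_inserted = isTRUE(slit_inserted), label = as.character(label)),
    class = "image_plane"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.4g A/px, %.3g s, slit %s%s\n",
              nrow(x$data), ncol(x$data), x$pixel_size_a, x$exposure_s,
              if (x$slit_inserted) "in" else "out",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) dim(x$data)

#' Filtered / unfiltered image pair
#'
#' Couples the unfiltered intensity image `I` with the zero-loss filtered
#' image `I_zl` of the same grid square.  `shift_px` records the
#' translation of the filtered image relative to the unfiltered one
#' (`(dy, dx)`, rows then columns); after [align_pair()] the filtered
#' plane has been resampled by the negated shift and `aligned` is `TRUE`.
#'
#' @param unfiltered,filtered [image_plane()] objects of identical shape
#'   and pixel size.
#' @param shift_px Translation `(dy, dx)` of filtered relative to
#'   unfiltered, in pixels.
#' @param aligned Whether the filtered plane is already resampled onto
#'   the unfiltered one.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(unfiltered, filtered, shift_px = c(0, 0),
                       aligned = FALSE) {
  stopifnot(inherits(unfiltered, "image_plane"),
            inherits(filtered, "image_plane"))
  if (!identical(dim(unfiltered$data), dim(filtered$data))) {
    ice_stop("domain_error", "pair planes differ in shape (%s vs %s)",
             paste(dim(unfiltered$data), collapse = "x"),
             paste(dim(filtered$data), collapse = "x"))
  }
  if (abs(unfiltered$pixel_size_a - filtered$pixel_size_a) >
      1e-6 * unfiltered$pixel_size_a) {
    ice_stop("domain_error", "pair planes differ in pixel size")
  }
  structure(
    list(unfiltered = unfiltered, filtered = filtered,
         shift_px = as.numeric(shift_px), aligned = isTRUE(aligned)),
    class = "image_pair"
  )
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d px, %.4g A/px, shift (%.2f, %.2f), %saligned\n",
              nrow(x$unfiltered$data), ncol(x$unfiltered$data),
              x$unfiltered$pixel_size_a, x$shift_px[1L], x$shift_px[2L],
              if (x$aligned) "" else "not "))
  invisible(x)
}

#' Bin an image by block averaging
#'
#' Block-mean pooling by an integer factor.  Mean pooling (rather than
#' summing) keeps intensity ratios, and therefore thickness values,
#' invariant under binning.  The pixel size is multiplied by the factor;
#' trailing rows/columns that do not fill a block are cropped with a
#' warning.
#'
#' @param plane An [image_plane()].
#' @param factor Integer binning factor >= 1 (4 is the usual survey
#'   setting).
#' @return The binned [image_plane()].
#' @export
bin_image <- function(plane, factor) {
  stopifnot(inherits(plane, "image_plane"))
  if (!is_count(factor) || factor < 1) {
    ice_stop("domain_error", "binning factor must be an integer >= 1")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(plane)
  m <- plane$data
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  if (nr * factor != nrow(m) || nc * factor != ncol(m)) {
    ice_warn("crop", "image %d x %d not divisible by %d; cropping to %d x %d",
             nrow(m), ncol(m), factor, nr * factor, nc * factor)
    m <- m[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  }
  # Average rows within blocks, then columns.
  dim(m) <- c(factor, nr, nc * factor)
  m <- colMeans(m)
  m <- t(m)
  dim(m) <- c(factor, nc, nr)
  m <- colMeans(m)
  m <- t(m)
  image_plane(m, pixel_size_a = plane$pixel_size_a * factor,
              exposure_s = plane$exposure_s,
              slit_inserted = plane$slit_inserted, label = plane$label)
}

#' Median-filter an image
#'
#' Per-pixel median over a square neighbourhood with reflected edge
#' padding; used to suppress counting noise before display or ratio
#' statistics.  `NA`/`NaN` pixels are ignored within each window (a
#' window with no finite value yields `NA`).
#'
#' @param plane An [image_plane()] or numeric matrix.
#' @param kernel Odd window size >= 1 (default 3, i.e. 3 x 3).
#' @return Same type as the input, filtered.
#' @export
median_filter_image <- function(plane, kernel = 3L) {
  if (!is_count(kernel) || kernel < 1 || kernel %% 2 == 0) {
    ice_stop("domain_error", "median filter kernel must be odd and >= 1, got %s",
             paste(kernel, collapse = ","))
  }
  if (kernel == 1L) return(plane)
  if (is.matrix(plane)) {
    return(median_filter_reflect(plane, as.integer(kernel)))
  }
  stopifnot(inherits(plane, "image_plane"))
  out <- plane
  out$data <- median_filter_reflect(plane$data, as.integer(kernel))
  out
}

#' Mean count rate of an image
#'
#' @param plane An [image_plane()].
#' @return Mean counts per pixel per second, `mean(data) / exposure_s`.
#' @export
mean_count_rate <- function(plane) {
  stopifnot(inherits(plane, "image_plane"))
  mean(plane$data) / plane$exposure_s
}
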