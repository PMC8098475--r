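# Registration of the filtered onto the unfiltered image.
#
# Inserting an energy shift for the zero-loss slit at low magnification
# introduces a lateral image shift between the two channels; per-pixel
# ratios are only meaningful after this translation is corrected.

#' Estimate the translation between the planes of a pair
#'
#' Phase correlation: the cross-power spectrum of the two planes is
#' whitened and inverse-transformed; its peak sits at the translation of
#' the filtered plane relative to the unfiltered one.  The peak position
#' is refined to sub-pixel precision by a separable parabolic fit over
#' the three correlation values around the maximum.
#'
#' @param pair An [image_pair()].
#' @return A list with `shift_px` (`(dy, dx)`, the displacement of
#'   filtered relative to unfiltered) and `confidence` (ratio of the main
#'   correlation peak to the strongest secondary peak; 0 for degenerate
#'   images).
#' @export
estimate_shift <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  a <- pair$unfiltered$data
  b <- pair$filtered$data
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    ice_warn("degenerate_image",
             "constant image: translation is undefined, returning (0, 0)")
    return(list(shift_px = c(0, 0), confidence = 0))
  }
  A <- fft(a - mean(a))
  B <- fft(b - mean(b))
  R <- Conj(A) * B
  mod <- Mod(R)
  R <- R / pmax(mod, .Machine$double.eps * max(mod))
  corr <- Re(fft(R, inverse = TRUE)) / length(R)
  nr <- nrow(corr); nc <- ncol(corr)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1L, ]
  py <- pk[[1L]]; px <- pk[[2L]]

  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  # Parabolic sub-pixel refinement along each axis.
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) return(0)  # not a proper maximum
    max(min((cm - cp) / (2 * den), 0.5), -0.5)
  }
  dy_sub <- refine(corr[wrap(py - 1L, nr), px], corr[py, px],
                   corr[wrap(py + 1L, nr), px])
  dx_sub <- refine(corr[py, wrap(px - 1L, nc)], corr[py, px],
                   corr[py, wrap(px + 1L, nc)])
  dy <- (py - 1L); if (dy > nr / 2) dy <- dy - nr
  dx <- (px - 1L); if (dx > nc / 2) dx <- dx - nc

  # Confidence: main peak against the strongest peak outside its 3x3
  # neighbourhood.
  masked <- corr
  masked[wrap(py + (-1:1), nr), wrap(px + (-1:1), nc)] <- -Inf
  second <- max(masked)
  confidence <- if (second > 0) corr[py, px] / second else Inf

  list(shift_px = c(dy + dy_sub, dx + dx_sub), confidence = confidence)
}

#' Resample the filtered plane onto the unfiltered one
#'
#' Translates the filtered plane by the negated shift (bilinear
#' interpolation, periodic boundary) so that both planes are in register.
#' Pixels wrapped in from the opposite border are not trustworthy; they
#' are excluded later by the validity mask of [log_attenuation_map()].
#'
#' @param pair An [image_pair()].
#' @param shift_px Translation `(dy, dx)` of filtered relative to
#'   unfiltered; estimated by [estimate_shift()] when `NULL`.
#' @param max_shift_frac Largest allowed `|shift|` as a fraction of each
#'   image dimension (default 0.25).
#' @return The aligned [image_pair()] (`aligned = TRUE`, `shift_px`
#'   recorded).
#' @export
align_pair <- function(pair, shift_px = NULL, max_shift_frac = 0.25) {
  stopifnot(inherits(pair, "image_pair"))
  if (is.null(shift_px)) {
    shift_px <- estimate_shift(pair)$shift_px
  }
  shift_px <- as.numeric(shift_px)
  dims <- dim(pair$unfiltered$data)
  if (abs(shift_px[1L]) >= max_shift_frac * dims[1L] ||
      abs(shift_px[2L]) >= max_shift_frac * dims[2L]) {
    ice_stop("alignment_failure",
             "shift (%.1f, %.1f) px exceeds %g%% of the image size",
             shift_px[1L], shift_px[2L], 100 * max_shift_frac)
  }
  out <- pair
  if (any(shift_px != 0)) {
    out$filtered$data <- translate_bilinear(pair$filtered$data,
                                            -shift_px[1L], -shift_px[2L])
  }
  out$shift_px <- shift_px
  out$aligned <- TRUE
  out
}
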