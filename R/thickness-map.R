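#' Thickness selection window
#'
#' The acquisition window in nm.  For small membrane proteins a window of
#' 20-40 nm is a good default; a practical starting point for other
#' projects is the expected particle size plus 5-20 nm.  Bounds are
#' inclusive on both sides.
#'
#' @param t_min_nm,t_max_nm Window bounds in nm, `0 <= t_min < t_max`.
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(t_min_nm = 20, t_max_nm = 40) {
  if (!is_number(t_min_nm) || !is_number(t_max_nm) ||
      t_min_nm < 0 || t_min_nm >= t_max_nm) {
    ice_stop("domain_error",
             "need 0 <= t_min_nm < t_max_nm, got (%s, %s)",
             paste(t_min_nm, collapse = ","), paste(t_max_nm, collapse = ","))
  }
  structure(list(t_min_nm = as.numeric(t_min_nm),
                 t_max_nm = as.numeric(t_max_nm)),
            class = "selection_policy")
}

# Validity margin implied by the wrap-around of the alignment resampling.
alignment_margin <- function(shift_px) {
  c(ceiling(abs(shift_px[1L])), ceiling(abs(shift_px[2L])))
}

#' Per-pixel log-attenuation of an aligned pair
#'
#' Forms the ratio image `I / I_zl` of the aligned pair, optionally
#' median-filters it (default 3 x 3) to tame counting noise, and returns
#' its natural log together with a validity mask.  Pixels where either
#' channel is non-positive, and border pixels corrupted by the alignment
#' wrap-around, are invalid.
#'
#' @param pair An aligned [image_pair()].
#' @param apply_median Median-filter the ratio image before the log.
#' @param median_kernel Window size for the median filter.
#' @return A list with matrices `log_attenuation` (`NaN` where invalid)
#'   and `valid` (logical).
#' @export
log_attenuation_map <- function(pair, apply_median = TRUE,
                                median_kernel = 3L) {
  stopifnot(inherits(pair, "image_pair"))
  if (!pair$aligned) {
    ice_stop("not_aligned", "pair must be aligned first (see align_pair())")
  }
  I <- pair$unfiltered$data
  Izl <- pair$filtered$data
  valid <- is.finite(I) & is.finite(Izl) & I > 0 & Izl > 0
  mar <- alignment_margin(pair$shift_px)
  if (mar[1L] > 0) {
    edge <- c(seq_len(mar[1L]), nrow(I) - seq_len(mar[1L]) + 1L)
    valid[edge, ] <- FALSE
  }
  if (mar[2L] > 0) {
    edge <- c(seq_len(mar[2L]), ncol(I) - seq_len(mar[2L]) + 1L)
    valid[, edge] <- FALSE
  }
  ratio <- I / Izl
  ratio[!valid] <- NaN
  if (apply_median && median_kernel > 1L) {
    ratio <- median_filter_image(ratio, median_kernel)
    ratio[!valid] <- NaN
  }
  lnr <- log(ratio)
  lnr[!is.finite(lnr)] <- NaN
  valid <- valid & is.finite(lnr)
  list(log_attenuation = lnr, valid = valid)
}

new_thickness_map <- function(thickness_nm, valid, profile, pixel_size_a) {
  structure(list(thickness_nm = thickness_nm, valid = valid,
                 profile = profile, pixel_size_a = pixel_size_a),
            class = "thickness_map")
}

#' Per-pixel thickness map from a filtered/unfiltered pair
#'
#' Applies the zero-loss relation `D = scale * ln(I/I_zl) - C` pixel by
#' pixel to the (optionally median-filtered) ratio image of an aligned
#' pair.  Thickness values are stored raw (unclamped, possibly slightly
#' negative over vacuum); invalid pixels carry `NaN` and are excluded
#' from all statistics.
#'
#' @inheritParams log_attenuation_map
#' @param profile A FILTER-method [calibration_profile()].
#' @return A `thickness_map`: matrices `thickness_nm` and `valid`, plus
#'   the profile and pixel size.
#' @export
thickness_map <- function(pair, profile, apply_median = TRUE,
                          median_kernel = 3L) {
  stopifnot(inherits(profile, "calibration_profile"))
  if (profile$method != "FILTER") {
    ice_stop("method_mismatch",
             "thickness_map() needs a FILTER profile; use thickness_map_als() for ALS")
  }
  la <- log_attenuation_map(pair, apply_median = apply_median,
                            median_kernel = median_kernel)
  d <- profile$scale_nm * la$log_attenuation - profile$correction_nm
  d[!la$valid] <- NaN
  new_thickness_map(d, la$valid, profile, pair$unfiltered$pixel_size_a)
}

#' Per-pixel thickness map by aperture-limited scattering
#'
#' Applies `D = lambda_ALS * ln(I0 / I)` pixel by pixel against a vacuum
#' reference measured inside an empty hole under the same imaging
#' settings.
#'
#' @param plane An [image_plane()].
#' @param reference A [vacuum_reference()].
#' @param profile An ALS-method [calibration_profile()].
#' @inheritParams log_attenuation_map
#' @return A `thickness_map`.
#' @export
thickness_map_als <- function(plane, reference, profile,
                              apply_median = TRUE, median_kernel = 3L) {
  stopifnot(inherits(plane, "image_plane"),
            inherits(reference, "vacuum_reference"),
            inherits(profile, "calibration_profile"))
  if (profile$method != "ALS") {
    ice_stop("method_mismatch", "thickness_map_als() needs an ALS profile")
  }
  I <- plane$data
  valid <- is.finite(I) & I > 0
  ratio <- reference$intensity / I
  ratio[!valid] <- NaN
  if (apply_median && median_kernel > 1L) {
    ratio <- median_filter_image(ratio, median_kernel)
    ratio[!valid] <- NaN
  }
  d <- profile$scale_nm * log(ratio)
  d[!is.finite(d)] <- NaN
  valid <- valid & is.finite(d)
  new_thickness_map(d, valid, profile, plane$pixel_size_a)
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$thickness_nm[x$valid]
  cat(sprintf("<thickness_map> %d x %d px (%.4g A/px), %d%% valid\n",
              nrow(x$thickness_nm), ncol(x$thickness_nm), x$pixel_size_a,
              round(100 * mean(x$valid))))
  if (length(v)) {
    q <- stats::quantile(v, c(0.05, 0.5, 0.95))
    cat(sprintf("  thickness nm: median %.1f, 5-95%% [%.1f, %.1f]\n",
                q[2L], q[1L], q[3L]))
  }
  invisible(x)
}

#' @export
summary.thickness_map <- function(object, ...) {
  v <- object$thickness_nm[object$valid]
  list(n_valid = length(v), n_total = length(object$valid),
       mean_nm = mean(v), median_nm = stats::median(v),
       sd_nm = stats::sd(v), range_nm = range(v))
}

#' Local thickness at a point
#'
#' Interactive-style point measurement: averages the ratio image
#' `I / I_zl` over a square box centred on the point (clipped at the
#' image border), then applies the zero-loss relation to the averaged
#' ratio.  Note this is mean-of-ratio; per-hole measurements in
#' [measure_holes()] use ratio-of-means instead, following acquisition
#' practice.
#'
#' @param pair An aligned [image_pair()].
#' @param point `(row, col)` pixel coordinates (1-based).
#' @param box_px Odd box size in pixels.
#' @param profile A FILTER-method [calibration_profile()].
#' @return Thickness in nm.
#' @export
local_thickness <- function(pair, point, box_px = 3L, profile) {
  stopifnot(inherits(pair, "image_pair"),
            inherits(profile, "calibration_profile"))
  if (profile$method != "FILTER") {
    ice_stop("method_mismatch", "local_thickness() needs a FILTER profile")
  }
  if (!pair$aligned) {
    ice_stop("not_aligned", "pair must be aligned first")
  }
  if (!is_count(box_px) || box_px < 1 || box_px %% 2 == 0) {
    ice_stop("domain_error", "box_px must be odd and >= 1")
  }
  dims <- dim(pair$unfiltered$data)
  r <- round(point[1L]); c <- round(point[2L])
  if (r < 1 || r > dims[1L] || c < 1 || c > dims[2L]) {
    ice_stop("domain_error", "point (%s, %s) lies outside the %d x %d image",
             point[1L], point[2L], dims[1L], dims[2L])
  }
  h <- (box_px - 1L) %/% 2L
  ri <- max(1L, r - h):min(dims[1L], r + h)
  ci <- max(1L, c - h):min(dims[2L], c + h)
  I <- pair$unfiltered$data[ri, ci]
  Izl <- pair$filtered$data[ri, ci]
  ok <- is.finite(I) & is.finite(Izl) & Izl > 0 & I > 0
  if (!any(ok)) {
    ice_stop("invalid_measurement", "no valid pixels in the measurement box")
  }
  ratio <- mean(I[ok] / Izl[ok])
  profile$scale_nm * log(ratio) - profile$correction_nm
}

# Classify clamped thickness against the policy window.
# Codes: 0 invalid, 1 below, 2 within, 3 above.
classify_thickness <- function(thickness_nm, valid, policy) {
  d <- pmax(thickness_nm, 0)
  cls <- matrix(0L, nrow(thickness_nm), ncol(thickness_nm))
  cls[valid & d < policy$t_min_nm] <- 1L
  cls[valid & d >= policy$t_min_nm & d <= policy$t_max_nm] <- 2L
  cls[valid & d > policy$t_max_nm] <- 3L
  cls
}

#' Render a thickness map as an RGB heatmap
#'
#' Classifies each valid pixel against the selection window (on clamped
#' thickness) and colors it in one of two conventions:
#' * `"DM"` (survey-display style): too thin red, within-window green,
#'   too thick uncolored (the grayscale base shows through).
#' * `"SERIALEM"` (target-display style): too thin magenta, within
#'   green, too thick blue.
#' Invalid pixels are always uncolored.  The overlay is blended onto a
#' grayscale base image at fixed alpha.
#'
#' @param map A [thickness_map()].
#' @param policy A [selection_policy()].
#' @param palette `"DM"` or `"SERIALEM"`.
#' @param base Optional [image_plane()] (e.g. the unfiltered image) used
#'   as the grayscale base; defaults to the clamped thickness map itself.
#' @param alpha Overlay opacity in `[0, 1]`.
#' @return An `nrow x ncol x 3` array of RGB values in `[0, 1]`, with
#'   attributes `class_counts` (invalid/below/within/above) and
#'   `palette`.
#' @export
render_heatmap <- function(map, policy = selection_policy(),
                           palette = c("DM", "SERIALEM"), base = NULL,
                           alpha = 0.5) {
  stopifnot(inherits(map, "thickness_map"),
            inherits(policy, "selection_policy"))
  palette <- match.arg(palette)
  cls <- classify_thickness(map$thickness_nm, map$valid, policy)
  base_m <- if (!is.null(base)) {
    stopifnot(inherits(base, "image_plane"))
    base$data
  } else {
    b <- pmax(map$thickness_nm, 0)
    b[!map$valid] <- 0
    b
  }
  rng <- range(base_m, finite = TRUE)
  gray <- if (diff(rng) > 0) (base_m - rng[1L]) / diff(rng) else base_m * 0
  gray[!is.finite(gray)] <- 0

  colors <- switch(palette,
    DM = list(`1` = c(1, 0, 0), `2` = c(0, 1, 0), `3` = NULL),
    SERIALEM = list(`1` = c(1, 0, 1), `2` = c(0, 1, 0), `3` = c(0, 0, 1))
  )
  rgb <- array(rep(gray, 3L), dim = c(nrow(gray), ncol(gray), 3L))
  for (code in c("1", "2", "3")) {
    col <- colors[[code]]
    if (is.null(col)) next
    sel <- cls == as.integer(code)
    if (!any(sel)) next
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * col[ch]
      rgb[, , ch] <- plane
    }
  }
  counts <- c(invalid = sum(cls == 0L), below = sum(cls == 1L),
              within = sum(cls == 2L), above = sum(cls == 3L))
  structure(rgb, class_counts = counts, palette = palette)
}

#' Write a rendered heatmap as PNG
#'
#' @param rgb Array from [render_heatmap()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write a thickness map as MRC plus a text sidecar
#'
#' The map is written as a float MRC (invalid pixels as `NaN` -> stored
#' as-is) and a human-readable sidecar `<path>.txt` records the
#' calibration profile and summary statistics.
#'
#' @param map A [thickness_map()].
#' @param path Output MRC path.
#' @param policy Optional [selection_policy()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_thickness_map <- function(map, path, policy = NULL) {
  stopifnot(inherits(map, "thickness_map"))
  d <- map$thickness_nm
  d[!map$valid] <- -9999  # MRC sentinel for invalid pixels
  write_image(image_plane(d, pixel_size_a = map$pixel_size_a),
              path, mode = 2L)
  s <- summary(map)
  p <- map$profile
  lines <- c(
    "icethick thickness map sidecar",
    sprintf("profile = %d kV / %s / %s", p$voltage_kv, p$regime, p$method),
    sprintf("scale_nm = %.10g", p$scale_nm),
    sprintf("correction_nm = %.10g", p$correction_nm),
    sprintf("pixel_size_a = %.10g", map$pixel_size_a),
    sprintf("invalid_sentinel = -9999"),
    sprintf("n_valid = %d / %d", s$n_valid, s$n_total),
    sprintf("mean_nm = %.4f", s$mean_nm),
    sprintf("median_nm = %.4f", s$median_nm),
    sprintf("sd_nm = %.4f", s$sd_nm)
  )
  if (!is.null(policy)) {
    lines <- c(lines, sprintf("policy_nm = [%g, %g]",
                              policy$t_min_nm, policy$t_max_nm))
  }
  writeLines(lines, paste0(path, ".txt"))
  invisible(path)
}
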