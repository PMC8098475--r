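#' Hole lattice of a holey support film
#'
#' Holey films (Quantifoil, UltraAuFoil, ...) carry a periodic lattice of
#' circular holes; its geometry is what makes hole detection robust at
#' survey magnification.
#'
#' @param origin_px `(row, col)` of one lattice node, 1-based pixels.
#' @param v1_px,v2_px Lattice basis vectors `(dr, dc)` in pixels;
#'   must be non-collinear and longer than twice the hole radius.
#' @param hole_radius_px Hole radius in pixels.
#' @param spacing_um Physical centre-to-centre spacing in micrometres.
#' @return An object of class `hole_lattice`.
#' @export
hole_lattice <- function(origin_px, v1_px, v2_px, hole_radius_px,
                         spacing_um = NA_real_) {
  v1 <- as.numeric(v1_px); v2 <- as.numeric(v2_px)
  cross <- v1[1L] * v2[2L] - v1[2L] * v2[1L]
  if (abs(cross) < 1e-9) {
    ice_stop("domain_error", "lattice basis vectors are collinear")
  }
  if (hole_radius_px <= 0 ||
      hole_radius_px >= min(sqrt(sum(v1^2)), sqrt(sum(v2^2))) / 2) {
    ice_stop("domain_error",
             "hole radius must be positive and below half the lattice spacing")
  }
  structure(list(origin_px = as.numeric(origin_px), v1_px = v1, v2_px = v2,
                 hole_radius_px = as.numeric(hole_radius_px),
                 spacing_um = as.numeric(spacing_um)),
            class = "hole_lattice")
}

#' @export
print.hole_lattice <- function(x, ...) {
  cat(sprintf(
    "<hole_lattice> |v1| = %.2f px, |v2| = %.2f px, hole radius %.2f px%s\n",
    sqrt(sum(x$v1_px^2)), sqrt(sum(x$v2_px^2)), x$hole_radius_px,
    if (is.finite(x$spacing_um)) sprintf(" (%.3g um pitch)", x$spacing_um)
    else ""))
  invisible(x)
}

# fftshift for autocorrelation display/peak search.
fftshift2 <- function(m) {
  roll_matrix(m, nrow(m) %/% 2L, ncol(m) %/% 2L)
}

# All lattice node centres falling inside an nr x nc image (optionally
# with a margin), together with their integer lattice indices.
lattice_nodes <- function(lattice, dims, margin = 0) {
  o <- lattice$origin_px; v1 <- lattice$v1_px; v2 <- lattice$v2_px
  basis <- cbind(v1, v2)
  inv <- solve(basis)
  corners <- rbind(c(1, 1), c(dims[1L], 1), c(1, dims[2L]), dims)
  lat <- t(inv %*% (t(corners) - o))
  i_range <- floor(min(lat[, 1L]) - 1):ceiling(max(lat[, 1L]) + 1)
  j_range <- floor(min(lat[, 2L]) - 1):ceiling(max(lat[, 2L]) + 1)
  grid <- expand.grid(i = i_range, j = j_range)
  centers <- t(o + basis %*% t(as.matrix(grid)))
  keep <- centers[, 1L] >= 1 + margin & centers[, 1L] <= dims[1L] - margin &
    centers[, 2L] >= 1 + margin & centers[, 2L] <= dims[2L] - margin
  data.frame(lat_i = grid$i[keep], lat_j = grid$j[keep],
             row_px = centers[keep, 1L], col_px = centers[keep, 2L])
}

# Sub-pixel refinement of a peak in a matrix by separable parabola.
refine_peak <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  off <- c(0, 0)
  if (r > 1 && r < nr) {
    den <- m[r - 1L, c] - 2 * m[r, c] + m[r + 1L, c]
    if (den < 0) off[1L] <- max(min((m[r - 1L, c] - m[r + 1L, c]) / (2 * den),
                                    0.5), -0.5)
  }
  if (c > 1 && c < nc) {
    den <- m[r, c - 1L] - 2 * m[r, c] + m[r, c + 1L]
    if (den < 0) off[2L] <- max(min((m[r, c - 1L] - m[r, c + 1L]) / (2 * den),
                                    0.5), -0.5)
  }
  c(r, c) + off
}

# Local maxima of a matrix (8-neighbourhood), returned as an index matrix.
local_maxima <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  inner <- m[2:(nr - 1L), 2:(nc - 1L)]
  ok <- inner > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & inner >= m[2:(nr - 1L) + dy, 2:(nc - 1L) + dx]
  }
  idx <- which(ok, arr.ind = TRUE)
  idx + 1L  # back to full-matrix coordinates
}

#' Estimate the hole lattice of a grid-square image
#'
#' The lattice basis is read off the autocorrelation of the image: the
#' two shortest non-collinear off-centre autocorrelation peaks are the
#' basis vectors (sub-pixel refined).  The hole radius is then estimated
#' from the bright-pixel area fraction: with one hole per unit cell,
#' `area_fraction = pi r^2 / |v1 x v2|`.
#'
#' @param plane An [image_plane()] of a grid square (>= 9 visible holes).
#' @param spacing_hint_um Optional known centre-to-centre spacing in um,
#'   used to restrict the peak search.
#' @return A [hole_lattice()].  The origin is placed on the strongest
#'   matched-filter response (see [detect_holes()] for per-hole centres).
#' @export
estimate_lattice <- function(plane, spacing_hint_um = NULL) {
  stopifnot(inherits(plane, "image_plane"))
  m <- plane$data
  nr <- nrow(m); nc <- ncol(m)
  if (stats::sd(m) == 0) {
    ice_stop("lattice_detection", "constant image: no periodic structure")
  }
  a <- m - mean(m)
  F <- fft(a)
  ac <- Re(fft(F * Conj(F), inverse = TRUE)) / length(a)
  ac <- fftshift2(ac)
  cy <- nr %/% 2L + 1L
  cx <- nc %/% 2L + 1L
  c0 <- ac[cy, cx]

  if (!is.null(spacing_hint_um)) {
    hint_px <- spacing_hint_um * 1e4 / plane$pixel_size_a
    rmin <- 0.6 * hint_px
    rmax <- 1.5 * hint_px
  } else {
    rmin <- 4
    rmax <- min(nr, nc) / 2 - 2
  }

  # 0.1 * c0 rejects spurious maxima of the noise autocorrelation while
  # keeping true lattice peaks, which carry a large share of the image
  # variance on periodic hole patterns.
  peaks <- local_maxima(ac, threshold = 0.1 * c0)
  if (nrow(peaks) == 0L) {
    ice_stop("lattice_detection", "no periodic structure found")
  }
  dy <- peaks[, 1L] - cy
  dx <- peaks[, 2L] - cx
  rad <- sqrt(dy^2 + dx^2)
  keep <- rad >= rmin & rad <= rmax
  if (!any(keep)) {
    ice_stop("lattice_detection",
             "no autocorrelation peak in the expected spacing range")
  }
  dy <- dy[keep]; dx <- dx[keep]; rad <- rad[keep]
  val <- ac[peaks[keep, , drop = FALSE]]
  ord <- order(rad, -val)
  dy <- dy[ord]; dx <- dx[ord]; rad <- rad[ord]

  v1 <- c(dy[1L], dx[1L])
  v2 <- NULL
  for (k in seq_along(dy)[-1L]) {
    cand <- c(dy[k], dx[k])
    sin_angle <- abs(v1[1L] * cand[2L] - v1[2L] * cand[1L]) /
      (sqrt(sum(v1^2)) * sqrt(sum(cand^2)))
    if (sin_angle > 0.35) {
      v2 <- cand
      break
    }
  }
  if (is.null(v2)) {
    ice_stop("lattice_detection", "no second non-collinear lattice direction")
  }
  sub1 <- refine_peak(ac, cy + v1[1L], cx + v1[2L]) - c(cy, cx)
  sub2 <- refine_peak(ac, cy + v2[1L], cx + v2[2L]) - c(cy, cx)
  # Canonical orientation: first nonzero component positive.
  fix_sign <- function(v) if (v[1L] < 0 || (v[1L] == 0 && v[2L] < 0)) -v else v
  v1 <- fix_sign(sub1); v2 <- fix_sign(sub2)

  # Hole radius from the bright-area fraction (holes are brighter than
  # the support film in the unfiltered channel).
  lo <- stats::quantile(m, 0.05); hi <- stats::quantile(m, 0.98)
  frac <- mean(m > (lo + hi) / 2)
  cell <- abs(v1[1L] * v2[2L] - v1[2L] * v2[1L])
  r <- sqrt(max(frac, 1e-6) * cell / pi)
  r <- min(r, 0.49 * min(sqrt(sum(v1^2)), sqrt(sum(v2^2))))

  # Anchor the origin on the strongest disk-matched-filter response.
  ncc <- disk_ncc(m, r)
  pk <- which(ncc == max(ncc), arr.ind = TRUE)[1L, ]
  origin <- refine_peak(ncc, pk[[1L]], pk[[2L]])

  hole_lattice(origin, v1, v2, r,
               spacing_um = sqrt(sum(v1^2)) * plane$pixel_size_a * 1e-4)
}

# Normalized cross-correlation of the image with a centred disk template
# inside a square window (side 2w+1).  Returns values in [-1, 1]; flat
# regions give 0.
disk_ncc <- function(m, radius) {
  w <- max(ceiling(1.3 * radius), ceiling(radius) + 2L)
  side <- 2L * w + 1L
  yy <- matrix(rep(-w:w, side), side, side)
  xx <- t(yy)
  disk <- (yy^2 + xx^2) <= radius^2
  npix <- side^2
  t0 <- disk - mean(disk)
  t_norm <- sqrt(sum(t0^2))
  ones <- matrix(1, side, side)
  num <- circ_xcorr(m, t0)
  s1 <- circ_xcorr(m, ones)
  s2 <- circ_xcorr(m^2, ones)
  denom <- sqrt(pmax(s2 - s1^2 / npix, 0)) * t_norm
  out <- num / pmax(denom, 1e-12)
  out[denom <= 1e-12] <- 0
  out
}

new_hole_set <- function(df, lattice = NULL) {
  structure(df, class = c("hole_set", "data.frame"), lattice = lattice)
}

#' Detect holes on the lattice of a grid-square image
#'
#' Scores every lattice node by the normalized cross-correlation of the
#' image with a disk template of the lattice's hole radius; the per-node
#' correlation peak within a snap radius gives the refined hole centre.
#' Nodes whose correlation stays below `min_ncc` are dropped (no hole
#' visible), and holes closer than `edge_margin_px` to the image border
#' are flagged `edge` and excluded from the default output.
#'
#' @param plane An [image_plane()] (the unfiltered channel).
#' @param lattice A [hole_lattice()], e.g. from [estimate_lattice()].
#' @param edge_margin_px Margin in pixels; defaults to the hole radius
#'   plus 2.
#' @param min_ncc Acceptance threshold on the correlation score.
#' @param include_edge Keep edge-flagged holes in the output.
#' @return A `hole_set`: a data frame with one row per detected hole
#'   (`id`, `lat_i`, `lat_j`, `row_px`, `col_px`, `score`, `mean_I`,
#'   `mean_Izl`, `thickness_nm`, `selected`, `group_id`, `flags`), with
#'   the lattice attached as an attribute.
#' @export
detect_holes <- function(plane, lattice, edge_margin_px = NULL,
                         min_ncc = 0.3, include_edge = FALSE) {
  stopifnot(inherits(plane, "image_plane"),
            inherits(lattice, "hole_lattice"))
  m <- plane$data
  dims <- dim(m)
  edge_margin_px <- edge_margin_px %||% (lattice$hole_radius_px + 2)
  ncc <- disk_ncc(m, lattice$hole_radius_px)
  nodes <- lattice_nodes(lattice, dims, margin = 0)
  snap <- max(2L, round(0.25 * min(sqrt(sum(lattice$v1_px^2)),
                                   sqrt(sum(lattice$v2_px^2)))))
  out <- vector("list", nrow(nodes))
  for (k in seq_len(nrow(nodes))) {
    r0 <- round(nodes$row_px[k]); c0 <- round(nodes$col_px[k])
    ri <- max(1L, r0 - snap):min(dims[1L], r0 + snap)
    ci <- max(1L, c0 - snap):min(dims[2L], c0 + snap)
    win <- ncc[ri, ci, drop = FALSE]
    pk <- which(win == max(win), arr.ind = TRUE)[1L, ]
    score <- win[pk[[1L]], pk[[2L]]]
    if (!is.finite(score) || score < min_ncc) next
    center <- refine_peak(ncc, ri[1L] + pk[[1L]] - 1L, ci[1L] + pk[[2L]] - 1L)
    edge <- center[1L] < edge_margin_px + 1 ||
      center[1L] > dims[1L] - edge_margin_px ||
      center[2L] < edge_margin_px + 1 ||
      center[2L] > dims[2L] - edge_margin_px
    out[[k]] <- data.frame(
      lat_i = nodes$lat_i[k], lat_j = nodes$lat_j[k],
      row_px = center[1L], col_px = center[2L], score = score,
      flags = if (edge) "edge" else ""
    )
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    df <- data.frame(lat_i = integer(0), lat_j = integer(0),
                     row_px = numeric(0), col_px = numeric(0),
                     score = numeric(0), flags = character(0))
  } else {
    df <- do.call(rbind, out)
  }
  # Deduplicate nodes that snapped onto the same correlation peak.
  if (nrow(df) > 1L) {
    key <- paste(round(df$row_px), round(df$col_px))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df <- df[order(df$lat_i, df$lat_j), , drop = FALSE]
  if (!include_edge) df <- df[df$flags != "edge", , drop = FALSE]
  n <- nrow(df)
  df <- data.frame(id = seq_len(n),
                   lat_i = df$lat_i, lat_j = df$lat_j,
                   row_px = df$row_px, col_px = df$col_px, score = df$score,
                   mean_I = rep(NA_real_, n), mean_Izl = rep(NA_real_, n),
                   thickness_nm = rep(NA_real_, n),
                   selected = logical(n),
                   group_id = rep(NA_integer_, n), flags = df$flags,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  new_hole_set(df, lattice)
}

#' @export
print.hole_set <- function(x, ...) {
  cat(sprintf("<hole_set> %d holes", nrow(x)))
  if (any(is.finite(x$thickness_nm))) {
    cat(sprintf(", thickness %.1f-%.1f nm",
                min(x$thickness_nm, na.rm = TRUE),
                max(x$thickness_nm, na.rm = TRUE)))
  }
  if (any(x$selected)) cat(sprintf(", %d selected", sum(x$selected)))
  cat("\n")
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat(sprintf("  below %d / within %d / above %d / flagged %d\n",
                s[["n_below"]], s[["n_within"]], s[["n_above"]],
                s[["n_flagged"]]))
  }
  invisible(x)
}

has_flag <- function(flags, what) {
  vapply(strsplit(flags, ",", fixed = TRUE),
         function(f) what %in% f, logical(1L))
}

add_flag <- function(flags, what) {
  ifelse(nzchar(flags), ifelse(has_flag(flags, what), flags,
                               paste(flags, what, sep = ",")), what)
}

# Integer pixel offsets of a disk of the given radius around a centre.
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  yy <- rep(-r:r, times = 2L * r + 1L)
  xx <- rep(-r:r, each = 2L * r + 1L)
  keep <- yy^2 + xx^2 <= radius^2
  cbind(dy = yy[keep], dx = xx[keep])
}

#' Measure per-hole intensities and thickness
#'
#' For each hole, averages the unfiltered (`I`) and filtered (`I_zl`)
#' intensities over a measurement disk of radius
#' `radius_fraction * hole_radius` centred on the hole, then converts the
#' *ratio of the means* to thickness with the zero-loss relation.  The
#' measurement disk must be kept inside the hole (default half the hole
#' radius), which makes the value robust to small centring errors.
#'
#' Holes whose disk contains fewer than 5 pixels are flagged
#' `low_confidence`; non-positive mean intensities flag `invalid` and
#' leave the thickness `NaN`.
#'
#' @param holes A `hole_set` from [detect_holes()].
#' @param pair An aligned [image_pair()].
#' @param profile A FILTER-method [calibration_profile()].
#' @param radius_fraction Measurement radius as a fraction of the hole
#'   radius, in `(0, 1]`.
#' @return The `hole_set` with `mean_I`, `mean_Izl` and `thickness_nm`
#'   filled in.
#' @export
measure_holes <- function(holes, pair, profile, radius_fraction = 0.5) {
  stopifnot(inherits(holes, "hole_set"), inherits(pair, "image_pair"),
            inherits(profile, "calibration_profile"))
  if (profile$method != "FILTER") {
    ice_stop("method_mismatch", "measure_holes() needs a FILTER profile")
  }
  if (!pair$aligned) {
    ice_stop("not_aligned", "pair must be aligned first")
  }
  if (!is_number(radius_fraction) || radius_fraction <= 0 ||
      radius_fraction > 1) {
    ice_stop("domain_error", "radius_fraction must be in (0, 1]")
  }
  lattice <- attr(holes, "lattice")
  if (is.null(lattice)) {
    ice_stop("domain_error", "hole_set carries no lattice attribute")
  }
  radius <- radius_fraction * lattice$hole_radius_px
  offs <- disk_offsets(radius)
  I <- pair$unfiltered$data
  Izl <- pair$filtered$data
  dims <- dim(I)
  for (k in seq_len(nrow(holes))) {
    r0 <- round(holes$row_px[k]); c0 <- round(holes$col_px[k])
    rr <- r0 + offs[, "dy"]; cc <- c0 + offs[, "dx"]
    keep <- rr >= 1 & rr <= dims[1L] & cc >= 1 & cc <= dims[2L]
    rr <- rr[keep]; cc <- cc[keep]
    if (length(rr) < 5L) {
      holes$flags[k] <- add_flag(holes$flags[k], "low_confidence")
    }
    if (length(rr) == 0L) {
      holes$flags[k] <- add_flag(holes$flags[k], "invalid")
      holes$thickness_nm[k] <- NaN
      next
    }
    idx <- cbind(rr, cc)
    mi <- mean(I[idx])
    mz <- mean(Izl[idx])
    holes$mean_I[k] <- mi
    holes$mean_Izl[k] <- mz
    if (!is.finite(mi) || !is.finite(mz) || mi <= 0 || mz <= 0) {
      holes$flags[k] <- add_flag(holes$flags[k], "invalid")
      holes$thickness_nm[k] <- NaN
    } else {
      holes$thickness_nm[k] <- profile$scale_nm * log(mi / mz) -
        profile$correction_nm
    }
  }
  holes
}

#' Select holes inside the thickness window
#'
#' A hole is selected iff its clamped thickness lies inside the window
#' (bounds inclusive) and it carries no disqualifying flag (`edge`,
#' `invalid`, `low_confidence`).  The returned set carries a summary
#' attribute `(n_below, n_within, n_above, n_flagged)`.
#'
#' @param holes A measured `hole_set`.
#' @param policy A [selection_policy()].
#' @return The `hole_set` with `selected` updated.
#' @export
select_holes <- function(holes, policy = selection_policy()) {
  stopifnot(inherits(holes, "hole_set"), inherits(policy, "selection_policy"))
  flagged <- nzchar(holes$flags) | !is.finite(holes$thickness_nm)
  d <- pmax(holes$thickness_nm, 0)
  within <- !flagged & d >= policy$t_min_nm & d <= policy$t_max_nm
  below <- !flagged & d < policy$t_min_nm
  above <- !flagged & d > policy$t_max_nm
  holes$selected <- within
  holes$group_id <- NA_integer_
  attr(holes, "summary") <- c(n_below = sum(below), n_within = sum(within),
                              n_above = sum(above), n_flagged = sum(flagged))
  attr(holes, "policy") <- policy
  holes
}

#' Re-apply threshold selection to stored thicknesses
#'
#' Adjusting the window after the fact only needs the stored per-hole
#' thicknesses (for example parsed back from an exported Navigator
#' file); nothing is re-measured.  Identical to [select_holes()] and
#' idempotent.
#'
#' @param holes A `hole_set` with `thickness_nm` present on every hole.
#' @param new_policy A [selection_policy()].
#' @return The re-selected `hole_set`.
#' @export
reselect_holes <- function(holes, new_policy) {
  stopifnot(inherits(holes, "hole_set"))
  missing <- which(is.na(holes$thickness_nm) & !nzchar(holes$flags))
  if (length(missing)) {
    ice_stop("missing_thickness",
             "no stored thickness for hole id(s): %s",
             paste(holes$id[missing], collapse = ", "))
  }
  select_holes(holes, new_policy)
}

#' Group selected holes into beam-image-shift acquisition patterns
#'
#' Tiles the lattice index plane into `rows x cols` blocks anchored at
#' the minimal lattice index of the selected holes, and forms one
#' acquisition group per non-empty block.  Groups contain only selected
#' holes (unselected lattice positions are skipped), may be partial, and
#' partition the selected set.  Each group's anchor is the member
#' nearest the group centroid (the natural stage position for the
#' beam-image-shift pattern).
#'
#' @param holes A selected `hole_set`.
#' @param pattern Integer `(rows, cols)` of the acquisition pattern,
#'   e.g. `c(3, 3)`.
#' @param lattice Optional [hole_lattice()]; defaults to the one attached
#'   to `holes`.
#' @return A list of class `acquisition_groups`; each element has `id`,
#'   `pattern`, `member_ids` and `anchor_id`.  The updated `hole_set`
#'   (with `group_id` filled in) is attached as attribute `holes`.
#' @export
group_holes <- function(holes, pattern = c(3L, 3L), lattice = NULL) {
  stopifnot(inherits(holes, "hole_set"))
  lattice <- lattice %||% attr(holes, "lattice")
  pattern <- as.integer(pattern)
  if (length(pattern) != 2L || any(pattern < 1L)) {
    ice_stop("domain_error", "pattern must be two integers >= 1")
  }
  sel <- holes[holes$selected, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(structure(list(), class = "acquisition_groups", holes = holes))
  }
  i0 <- min(sel$lat_i); j0 <- min(sel$lat_j)
  gi <- (sel$lat_i - i0) %/% pattern[1L]
  gj <- (sel$lat_j - j0) %/% pattern[2L]
  key <- paste(gi, gj, sep = "/")
  groups <- list()
  gid <- 0L
  for (k in unique(key)) {
    gid <- gid + 1L
    members <- sel[key == k, , drop = FALSE]
    centroid <- c(mean(members$row_px), mean(members$col_px))
    d2 <- (members$row_px - centroid[1L])^2 +
      (members$col_px - centroid[2L])^2
    groups[[gid]] <- list(id = gid, pattern = pattern,
                          member_ids = members$id,
                          anchor_id = members$id[which.min(d2)])
    holes$group_id[match(members$id, holes$id)] <- gid
  }
  structure(groups, class = "acquisition_groups", holes = holes)
}

#' @export
print.acquisition_groups <- function(x, ...) {
  sizes <- vapply(x, function(g) length(g$member_ids), integer(1L))
  cat(sprintf("<acquisition_groups> %d group(s), %d hole(s)",
              length(x), sum(sizes)))
  if (length(x)) {
    cat(sprintf(", pattern %dx%d, sizes %s",
                x[[1L]]$pattern[1L], x[[1L]]$pattern[2L],
                paste(sizes, collapse = "/")))
  }
  cat("\n")
  invisible(x)
}

#' Read / write hole tables as CSV
#'
#' Columns: `id`, `lat_i`, `lat_j`, `row_px`, `col_px`, `score`,
#' `mean_I`, `mean_Izl`, `thickness_nm`, `selected`, `group_id`, `flags`.
#'
#' @param holes A `hole_set`.
#' @param path File path.
#' @return The path (write) or a `hole_set` (read).
#' @export
write_holes_csv <- function(holes, path) {
  stopifnot(inherits(holes, "hole_set"))
  utils::write.csv(as.data.frame(holes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_holes_csv
#' @export
read_holes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$flags[is.na(df$flags)] <- ""
  df$selected <- as.logical(df$selected)
  new_hole_set(df)
}

#' Correlate per-hole thickness with an external quality metric
#'
#' Joins a per-image quality table (typically the CTF-fit resolution of
#' the micrograph acquired in each hole) onto the measured holes, bins
#' the quality metric over thickness, and reports the Spearman rank
#' correlation.  Thicker ice carries less high-resolution signal, so on
#' real data the correlation between thickness and CTF resolution (in
#' Angstrom, larger = worse) is positive.
#'
#' @param holes A measured `hole_set`.
#' @param quality_table Data frame with columns `id` and
#'   `ctf_resolution_a`.
#' @param bin_width_nm Thickness bin width for the binned summary.
#' @return A list of class `quality_correlation`: `table` (joined rows),
#'   `binned` (mean resolution per thickness bin), `spearman_rho`,
#'   `p_value`.
#' @export
correlate_quality <- function(holes, quality_table, bin_width_nm = 10) {
  stopifnot(inherits(holes, "hole_set"))
  if (!all(c("id", "ctf_resolution_a") %in% names(quality_table))) {
    ice_stop("parse_error",
             "quality table needs columns 'id' and 'ctf_resolution_a'")
  }
  joined <- merge(as.data.frame(holes)[, c("id", "thickness_nm")],
                  quality_table[, c("id", "ctf_resolution_a")], by = "id")
  joined <- joined[is.finite(joined$thickness_nm) &
                     is.finite(joined$ctf_resolution_a), , drop = FALSE]
  if (nrow(joined) == 0L) {
    ice_stop("empty_join", "no quality rows match the measured holes")
  }
  d <- pmax(joined$thickness_nm, 0)
  breaks <- seq(0, max(d) + bin_width_nm, by = bin_width_nm)
  bins <- cut(d, breaks, include.lowest = TRUE, right = FALSE)
  binned <- stats::aggregate(
    list(mean_ctf_resolution_a = joined$ctf_resolution_a,
         n = rep(1L, nrow(joined))),
    by = list(thickness_bin = bins),
    FUN = function(x) if (is.integer(x)) sum(x) else mean(x)
  )
  ct <- suppressWarnings(
    stats::cor.test(d, joined$ctf_resolution_a, method = "spearman")
  )
  structure(list(table = joined, binned = binned,
                 spearman_rho = unname(ct$estimate),
                 p_value = ct$p.value),
            class = "quality_correlation")
}

#' @export
print.quality_correlation <- function(x, ...) {
  cat(sprintf(
    "<quality_correlation> n = %d, Spearman rho = %.3f (p = %.3g)\n",
    nrow(x$table), x$spearman_rho, x$p_value))
  print(x$binned, row.names = FALSE)
  invisible(x)
}

#' Rescale a hole set to a different sampling
#'
#' Maps hole centres and the lattice between sampling grids (e.g. from
#' the fourfold-binned survey image, where detection is cheapest, back
#' to the native image, where per-hole intensity sums carry the most
#' counts and the disk boundary is sharpest).  Pixel centre `(1, 1)` of
#' the coarse grid corresponds to the centre of its block in the fine
#' grid.
#'
#' @param holes A `hole_set`.
#' @param factor Sampling ratio: > 1 maps binned coordinates to native
#'   ones (e.g. 4 for a fourfold-binned survey).
#' @return The rescaled `hole_set` (lattice attribute rescaled too).
#' @export
scale_holes <- function(holes, factor) {
  stopifnot(inherits(holes, "hole_set"))
  if (!is_number(factor) || factor <= 0) {
    ice_stop("domain_error", "factor must be > 0")
  }
  holes$row_px <- (holes$row_px - 0.5) * factor + 0.5
  holes$col_px <- (holes$col_px - 0.5) * factor + 0.5
  lattice <- attr(holes, "lattice")
  if (!is.null(lattice)) {
    lattice$origin_px <- (lattice$origin_px - 0.5) * factor + 0.5
    lattice$v1_px <- lattice$v1_px * factor
    lattice$v2_px <- lattice$v2_px * factor
    lattice$hole_radius_px <- lattice$hole_radius_px * factor
    attr(holes, "lattice") <- lattice
  }
  holes
}
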