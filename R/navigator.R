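# SerialEM Navigator (autodoc) export and re-import.
#
# One [Item = n] section per hole; the thickness travels in the Note
# ("<thickness> nm", 0.1 nm precision), the selection in Acquire, and
# the thickness class in Color (0 = within the window, 1 = below,
# 2 = above, 3 = unmeasured/flagged).  Stage coordinates are in
# micrometres.

NAV_COLOR_WITHIN <- 0L
NAV_COLOR_BELOW <- 1L
NAV_COLOR_ABOVE <- 2L
NAV_COLOR_OTHER <- 3L

#' Stage transform from pixel coordinates
#'
#' Affine map from image pixels `(row, col)` to stage micrometres
#' `(x, y)`: `x = a11*col + a12*row + tx`, `y = a21*col + a22*row + ty`.
#' The default is a pure scaling by the pixel size with no rotation.
#'
#' @param pixel_size_a Pixel size in Angstrom per pixel (used for the
#'   default scaling transform).
#' @param matrix_2x2 Optional 2 x 2 linear part (overrides the scaling).
#' @param offset_um Stage offset `(x, y)` in micrometres.
#' @return A list of class `stage_transform`.
#' @export
stage_transform <- function(pixel_size_a = NULL, matrix_2x2 = NULL,
                            offset_um = c(0, 0)) {
  if (is.null(matrix_2x2)) {
    if (is.null(pixel_size_a)) {
      ice_stop("domain_error",
               "either pixel_size_a or matrix_2x2 must be given")
    }
    s <- pixel_size_a * 1e-4  # Angstrom/px -> um/px
    matrix_2x2 <- matrix(c(s, 0, 0, s), 2L, 2L)
  }
  matrix_2x2 <- matrix(as.numeric(matrix_2x2), 2L, 2L)
  if (abs(det(matrix_2x2)) < 1e-12) {
    ice_stop("singular_transform", "stage transform matrix is singular")
  }
  structure(list(A = matrix_2x2, offset_um = as.numeric(offset_um)),
            class = "stage_transform")
}

apply_stage_transform <- function(tf, row_px, col_px) {
  xy <- tf$A %*% rbind(col_px, row_px)
  list(x = xy[1L, ] + tf$offset_um[1L], y = xy[2L, ] + tf$offset_um[2L])
}

nav_color <- function(thickness_nm, flags, policy) {
  d <- pmax(thickness_nm, 0)
  out <- rep(NAV_COLOR_OTHER, length(d))
  ok <- is.finite(d) & !nzchar(flags)
  out[ok & d < policy$t_min_nm] <- NAV_COLOR_BELOW
  out[ok & d >= policy$t_min_nm & d <= policy$t_max_nm] <- NAV_COLOR_WITHIN
  out[ok & d > policy$t_max_nm] <- NAV_COLOR_ABOVE
  out
}

#' Export holes as a SerialEM Navigator autodoc
#'
#' Writes one Navigator item per hole, ordered by hole id: stage
#' coordinates through the given transform, the thickness in the Note
#' (rounded to 0.1 nm), `Acquire = 1` for selected holes, a Color index
#' for the thickness class, and the acquisition `GroupId` when groups
#' are given.  Lines end in LF; [parse_navigator()] also accepts CRLF.
#'
#' @param holes A measured `hole_set`.
#' @param path Output file path (or `NULL` to return the lines).
#' @param groups Optional `acquisition_groups` from [group_holes()].
#' @param transform A [stage_transform()]; defaults to pixel-size scaling
#'   when `pixel_size_a` is given.
#' @param policy The [selection_policy()] used for the Color classes.
#' @param pixel_size_a Pixel size for the default transform.
#' @return The file path (or the character vector of lines), invisibly.
#' @export
export_navigator <- function(holes, path = NULL, groups = NULL,
                             transform = NULL, policy = NULL,
                             pixel_size_a = NULL) {
  stopifnot(inherits(holes, "hole_set"))
  policy <- policy %||% attr(holes, "policy") %||% selection_policy()
  if (is.null(transform)) {
    ps <- pixel_size_a %||% attr(holes, "lattice")$spacing_um
    if (is.null(pixel_size_a)) {
      # fall back to an identity-scaled transform in pixel units
      transform <- stage_transform(matrix_2x2 = diag(2L))
    } else {
      transform <- stage_transform(pixel_size_a = pixel_size_a)
    }
  }
  stopifnot(inherits(transform, "stage_transform"))
  holes <- holes[order(holes$id), , drop = FALSE]
  lines <- c("AdocVersion = 2.00", "")
  if (nrow(holes)) {
    xy <- apply_stage_transform(transform, holes$row_px, holes$col_px)
    color <- nav_color(holes$thickness_nm, holes$flags, policy)
    gid <- holes$group_id
    for (k in seq_len(nrow(holes))) {
      note <- if (is.finite(holes$thickness_nm[k])) {
        sprintf("%.1f nm", holes$thickness_nm[k])
      } else {
        "no thickness"
      }
      lines <- c(lines,
        sprintf("[Item = %d]", holes$id[k]),
        sprintf("StageXYZ = %.10g %.10g 0", xy$x[k], xy$y[k]),
        sprintf("Note = %s", note),
        sprintf("Acquire = %d", as.integer(holes$selected[k])),
        sprintf("Color = %d", color[k]),
        if (!is.na(gid[k])) sprintf("GroupId = %d", gid[k]) else NULL,
        "")
    }
  }
  if (is.null(path)) return(invisible(lines))
  con <- file(path, "wb")  # binary mode keeps LF endings on any platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Parse a Navigator autodoc back into a hole table
#'
#' Recovers stage coordinates, the thickness stored in the Note, the
#' Acquire flag, Color and GroupId from a file written by
#' [export_navigator()] (or any autodoc using the same keys).  CRLF line
#' endings are accepted.
#'
#' @param path Navigator file path.
#' @return A `hole_set` with `row_px`/`col_px` carrying the *stage*
#'   coordinates (y, x in micrometres unless the export transform was an
#'   identity), suitable for [reselect_holes()].
#' @export
parse_navigator <- function(path) {
  if (!file.exists(path)) {
    ice_stop("parse_error", "navigator file not found: %s", path)
  }
  lines <- gsub("\r$", "", readLines(path))
  items <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) items[[length(items) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (grepl("^\\[Item\\s*=", ln)) {
      flush()
      cur <- list(id = as.integer(sub("^\\[Item\\s*=\\s*(\\d+)\\s*\\]$",
                                      "\\1", ln)))
    } else if (!is.null(cur) && grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexec("^(\\S+)\\s*=\\s*(.*)$", ln))[[1L]]
      if (length(kv) == 3L) cur[[kv[2L]]] <- kv[3L]
    }
  }
  flush()
  n <- length(items)
  df <- data.frame(
    id = integer(n), lat_i = NA_integer_, lat_j = NA_integer_,
    row_px = NA_real_, col_px = NA_real_, score = NA_real_,
    mean_I = NA_real_, mean_Izl = NA_real_, thickness_nm = NA_real_,
    selected = FALSE, group_id = NA_integer_, flags = "",
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    it <- items[[k]]
    df$id[k] <- it$id
    if (!is.null(it$StageXYZ)) {
      xyz <- as.numeric(strsplit(trimws(it$StageXYZ), "\\s+")[[1L]])
      df$col_px[k] <- xyz[1L]
      df$row_px[k] <- xyz[2L]
    }
    if (!is.null(it$Note)) {
      hit <- regmatches(it$Note,
                        regexec("(-?[0-9.]+)\\s*nm", it$Note))[[1L]]
      if (length(hit) == 2L) df$thickness_nm[k] <- as.numeric(hit[2L])
      else df$flags[k] <- "invalid"
    }
    if (!is.null(it$Acquire)) df$selected[k] <- it$Acquire == "1"
    if (!is.null(it$GroupId)) df$group_id[k] <- as.integer(it$GroupId)
  }
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  new_hole_set(df)
}
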