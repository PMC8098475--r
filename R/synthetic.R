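# Synthetic grid-square simulator.
#
# Forward model of the zero-loss measurement on a holey film: a periodic
# lattice of circular holes in a darker support film, a spatially
# varying ice-thickness field D(px), zero-loss attenuation
# exp(-(D + C)/lambda) in the filtered channel, an empty-hole intensity
# slightly above open vacuum, an optional lateral shift of the filtered
# image (the energy-shift artefact), and Poisson counting noise.

#' Build a thickness field for the simulator
#'
#' @param kind `"uniform"` (constant), `"gradient"` (linear ramp across
#'   columns) or `"blobs"` (smoothed Gaussian random field, clipped at 0).
#' @param shape `(rows, cols)` of the field.
#' @param value Constant value for `"uniform"`, nm.
#' @param from,to Ramp endpoints for `"gradient"`, nm (first to last
#'   column).
#' @param mean_nm,sd_nm Target mean and standard deviation for `"blobs"`.
#' @param smooth_px Gaussian smoothing length for `"blobs"`, pixels.
#' @param seed RNG seed for `"blobs"`.
#' @return A numeric matrix of thicknesses in nm.
#' @export
make_thickness_field <- function(kind = c("uniform", "gradient", "blobs"),
                                 shape, value = 30, from = 10, to = 70,
                                 mean_nm = 30, sd_nm = 10,
                                 smooth_px = max(shape) / 16, seed = NULL) {
  kind <- match.arg(kind)
  nr <- shape[1L]; nc <- shape[2L]
  switch(kind,
    uniform = {
      if (value < 0) ice_stop("domain_error", "thickness must be >= 0")
      matrix(value, nr, nc)
    },
    gradient = {
      if (from < 0 || to < 0) ice_stop("domain_error", "thickness must be >= 0")
      ramp <- seq(from, to, length.out = nc)
      matrix(ramp, nr, nc, byrow = TRUE)
    },
    blobs = {
      z <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
      # Gaussian smoothing via FFT (periodic boundary).
      fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
      fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
      gy <- exp(-2 * (pi * smooth_px * fy)^2)
      gx <- exp(-2 * (pi * smooth_px * fx)^2)
      kern <- outer(gy, gx)
      zs <- Re(fft(fft(z) * kern, inverse = TRUE)) / length(z)
      zs <- (zs - mean(zs)) / stats::sd(zs)
      pmax(mean_nm + sd_nm * zs, 0)
    }
  )
}

#' Synthetic grid-square scene
#'
#' Ground-truth description of a simulated grid square.  Defaults mirror
#' a 200 kV survey acquisition: 10.7 counts per pixel per second at 1 s
#' exposure, 144.6 Angstrom native pixels, and a Quantifoil R1.2/1.3-like
#' geometry (2.5 um hole pitch, 0.6 um hole radius).  The empty-hole
#' offset is modeled phenomenologically as a constant extra attenuation
#' `vacuum_offset_nm` in the filtered channel - exactly the effect the
#' correction term of the measurement profile removes - and the
#' empty-hole intensity exceeds open vacuum by `hole_open_vacuum_factor`.
#'
#' @param image_shape `(rows, cols)` of the simulated images.
#' @param pixel_size_a Pixel size in Angstrom per pixel.
#' @param spacing_um Hole centre-to-centre spacing, um.
#' @param hole_radius_um Hole radius, um.
#' @param lattice_angle_deg Rotation of the (square) hole lattice.
#' @param origin_px Optional `(row, col)` of one hole centre.
#' @param thickness_field Matrix of D(row, col) in nm (see
#'   [make_thickness_field()]), or a single number for uniform ice.
#' @param profile Generative [calibration_profile()] (FILTER method).
#' @param vacuum_offset_nm Generative empty-hole offset C, nm.
#' @param film_transmission Intensity factor of the support film relative
#'   to open vacuum, in (0, 1).
#' @param hole_open_vacuum_factor Factor (>= 1) by which empty-hole
#'   intensity exceeds open vacuum.
#' @param incident_rate Counts per pixel per second over open vacuum.
#' @param exposure_s Exposure time, s.
#' @param filtered_shift_px `(dy, dx)` translation applied to the
#'   filtered image (energy-shift artefact).
#' @param noise Apply Poisson counting noise.
#' @param seed Single RNG seed; all simulator randomness flows from it.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(image_shape = c(2048L, 2048L),
                            pixel_size_a = 144.6,
                            spacing_um = 2.5,
                            hole_radius_um = 0.6,
                            lattice_angle_deg = 0,
                            origin_px = NULL,
                            thickness_field = 30,
                            profile = default_profile(200, "M_SA", "FILTER"),
                            vacuum_offset_nm = profile$correction_nm,
                            film_transmission = 0.4,
                            hole_open_vacuum_factor = 1.02,
                            incident_rate = 10.7,
                            exposure_s = 1,
                            filtered_shift_px = c(0, 0),
                            noise = TRUE,
                            seed = 1L) {
  stopifnot(inherits(profile, "calibration_profile"))
  if (profile$method != "FILTER") {
    ice_stop("method_mismatch", "the simulator generates filter-method pairs")
  }
  if (!is_number(incident_rate) || incident_rate <= 0) {
    ice_stop("domain_error", "incident_rate must be > 0")
  }
  if (!is_number(film_transmission) || film_transmission <= 0 ||
      film_transmission >= 1) {
    ice_stop("domain_error", "film_transmission must be in (0, 1)")
  }
  if (!is_number(hole_open_vacuum_factor) || hole_open_vacuum_factor < 1) {
    ice_stop("domain_error", "hole_open_vacuum_factor must be >= 1")
  }
  if (!is_number(vacuum_offset_nm) || vacuum_offset_nm < 0) {
    ice_stop("domain_error", "vacuum_offset_nm must be >= 0")
  }
  image_shape <- as.integer(image_shape)
  if (is.matrix(thickness_field)) {
    if (!identical(dim(thickness_field), image_shape)) {
      ice_stop("domain_error",
               "thickness_field dimensions must match image_shape")
    }
  } else if (is_number(thickness_field)) {
    thickness_field <- matrix(as.numeric(thickness_field),
                              image_shape[1L], image_shape[2L])
  } else {
    ice_stop("domain_error",
             "thickness_field must be a matrix or a single number")
  }
  if (any(thickness_field < 0)) {
    ice_stop("domain_error", "thickness_field must be >= 0 everywhere")
  }
  spacing_px <- spacing_um * 1e4 / pixel_size_a
  radius_px <- hole_radius_um * 1e4 / pixel_size_a
  ang <- lattice_angle_deg * pi / 180
  v1 <- spacing_px * c(cos(ang), sin(ang))
  v2 <- spacing_px * c(-sin(ang), cos(ang))
  origin_px <- origin_px %||% (image_shape / 2 + c(0.5, 0.5))
  lattice <- hole_lattice(origin_px, v1, v2, radius_px,
                          spacing_um = spacing_um)
  structure(
    list(image_shape = image_shape, pixel_size_a = pixel_size_a,
         lattice = lattice, thickness_field = thickness_field,
         profile = profile, vacuum_offset_nm = vacuum_offset_nm,
         film_transmission = film_transmission,
         hole_open_vacuum_factor = hole_open_vacuum_factor,
         incident_rate = incident_rate, exposure_s = exposure_s,
         filtered_shift_px = as.numeric(filtered_shift_px),
         noise = isTRUE(noise), seed = seed),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px @ %.4g A/px, pitch %.3g um, r %.3g um\n",
    x$image_shape[1L], x$image_shape[2L], x$pixel_size_a,
    x$lattice$spacing_um, x$lattice$hole_radius_px * x$pixel_size_a * 1e-4))
  cat(sprintf(
    "  rate %.3g counts/px/s, %.3g s, C %.3g nm, lambda %.4g nm, noise %s, seed %s\n",
    x$incident_rate, x$exposure_s, x$vacuum_offset_nm, x$profile$scale_nm,
    x$noise, format(x$seed)))
  invisible(x)
}

# Boolean hole mask for a scene, plus the node table.
scene_hole_mask <- function(scene) {
  dims <- scene$image_shape
  lattice <- scene$lattice
  nodes <- lattice_nodes(lattice, dims,
                         margin = -lattice$hole_radius_px)
  mask <- matrix(FALSE, dims[1L], dims[2L])
  r <- lattice$hole_radius_px
  ri <- ceiling(r)
  for (k in seq_len(nrow(nodes))) {
    rc <- nodes$row_px[k]; cc <- nodes$col_px[k]
    rows <- max(1L, floor(rc - ri)):min(dims[1L], ceiling(rc + ri))
    cols <- max(1L, floor(cc - ri)):min(dims[2L], ceiling(cc + ri))
    if (!length(rows) || !length(cols)) next
    sub <- outer((rows - rc)^2, (cols - cc)^2, `+`) <= r^2
    mask[rows, cols] <- mask[rows, cols] | sub
  }
  list(mask = mask, nodes = nodes)
}

#' Simulate a filtered/unfiltered grid-square image pair
#'
#' Forward model: unfiltered intensity is
#' `incident_rate * exposure * hole_open_vacuum_factor` inside holes and
#' `incident_rate * exposure * film_transmission` over the film; the
#' filtered channel multiplies in the zero-loss attenuation
#' `exp(-(D + C)/lambda)` (D = 0 over the film), is translated by the
#' scene's `filtered_shift_px`, and both channels receive independent
#' Poisson noise.  The truth table lists, per hole fully inside the
#' image, the disk-averaged thickness over the default measurement disk
#' (half the hole radius).
#'
#' @param scene A [synthetic_scene()].
#' @return A list with `pair` (an [image_pair()], unaligned when the
#'   scene shifts the filtered image), `truth` (data frame: `id`,
#'   `lat_i`, `lat_j`, `row_px`, `col_px`, `true_mean_thickness_nm`,
#'   `edge`) and `lattice` (the ground-truth [hole_lattice()]).
#' @export
simulate_pair <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dims <- scene$image_shape
  hm <- scene_hole_mask(scene)
  mask <- hm$mask
  base <- scene$incident_rate * scene$exposure_s
  I <- matrix(base * scene$film_transmission, dims[1L], dims[2L])
  I[mask] <- base * scene$hole_open_vacuum_factor
  d_eff <- matrix(0, dims[1L], dims[2L])
  d_eff[mask] <- scene$thickness_field[mask]
  atten <- exp(-(d_eff + scene$vacuum_offset_nm) / scene$profile$scale_nm)
  Izl <- I * atten
  if (any(scene$filtered_shift_px != 0)) {
    Izl <- translate_bilinear(Izl, scene$filtered_shift_px[1L],
                              scene$filtered_shift_px[2L])
  }
  if (scene$noise) {
    with_seed(scene$seed, {
      I <- matrix(stats::rpois(length(I), I), dims[1L], dims[2L])
      Izl <- matrix(stats::rpois(length(Izl), Izl), dims[1L], dims[2L])
    })
  }
  unfiltered <- image_plane(I, pixel_size_a = scene$pixel_size_a,
                            exposure_s = scene$exposure_s,
                            slit_inserted = FALSE, label = "synthetic I")
  filtered <- image_plane(Izl, pixel_size_a = scene$pixel_size_a,
                          exposure_s = scene$exposure_s,
                          slit_inserted = TRUE, label = "synthetic Izl")
  pair <- image_pair(unfiltered, filtered,
                     shift_px = scene$filtered_shift_px,
                     aligned = all(scene$filtered_shift_px == 0))

  lattice <- scene$lattice
  nodes <- lattice_nodes(lattice, dims, margin = -lattice$hole_radius_px)
  inside <- nodes$row_px - lattice$hole_radius_px >= 1 &
    nodes$row_px + lattice$hole_radius_px <= dims[1L] &
    nodes$col_px - lattice$hole_radius_px >= 1 &
    nodes$col_px + lattice$hole_radius_px <= dims[2L]
  nodes <- nodes[inside, , drop = FALSE]
  nodes <- nodes[order(nodes$lat_i, nodes$lat_j), , drop = FALSE]
  offs <- disk_offsets(0.5 * lattice$hole_radius_px)
  margin <- lattice$hole_radius_px + 2
  truth <- data.frame(
    id = seq_len(nrow(nodes)), lat_i = nodes$lat_i, lat_j = nodes$lat_j,
    row_px = nodes$row_px, col_px = nodes$col_px,
    true_mean_thickness_nm = NA_real_,
    edge = nodes$row_px < margin + 1 | nodes$row_px > dims[1L] - margin |
      nodes$col_px < margin + 1 | nodes$col_px > dims[2L] - margin
  )
  for (k in seq_len(nrow(truth))) {
    rr <- round(truth$row_px[k]) + offs[, "dy"]
    cc <- round(truth$col_px[k]) + offs[, "dx"]
    keep <- rr >= 1 & rr <= dims[1L] & cc >= 1 & cc <= dims[2L]
    truth$true_mean_thickness_nm[k] <-
      mean(scene$thickness_field[cbind(rr[keep], cc[keep])])
  }
  list(pair = pair, truth = truth, lattice = lattice)
}

#' Simulate a lambda-calibration data set
#'
#' Stands in for a tomography calibration session: `n_holes` thicknesses
#' drawn uniformly from `thickness_range`, exact log-attenuations
#' `(D + C)/lambda`, and true thicknesses observed with Gaussian noise
#' (floored at 0).  Three vacuum samples (D = 0) are appended so the
#' correction term is identifiable.
#'
#' @param true_lambda_nm Generative scaling constant, nm.
#' @param true_c_nm Generative correction term, nm.
#' @param n_holes Number of ice samples (>= 2).
#' @param thickness_range `(min, max)` thickness in nm.
#' @param noise_sd_nm SD of the thickness observation noise, nm.
#' @param seed RNG seed.
#' @return A [calibration_samples()] table.
#' @export
simulate_calibration_set <- function(true_lambda_nm, true_c_nm = 0,
                                     n_holes = 20,
                                     thickness_range = c(10, 100),
                                     noise_sd_nm = 5, seed = 1L) {
  if (!is_count(n_holes) || n_holes < 2) {
    ice_stop("domain_error", "n_holes must be an integer >= 2")
  }
  if (length(thickness_range) != 2L ||
      thickness_range[1L] < 0 || diff(thickness_range) <= 0) {
    ice_stop("domain_error", "thickness_range must be increasing and >= 0")
  }
  with_seed(seed, {
    d <- stats::runif(n_holes, thickness_range[1L], thickness_range[2L])
    obs <- pmax(d + stats::rnorm(n_holes, sd = noise_sd_nm), 0)
    lnr <- (d + true_c_nm) / true_lambda_nm
    vac_lnr <- rep(true_c_nm / true_lambda_nm, 3L)
    calibration_samples(
      log_attenuation = c(lnr, vac_lnr),
      true_thickness_nm = c(obs, 0, 0, 0),
      is_vacuum = c(rep(FALSE, n_holes), rep(TRUE, 3L))
    )
  })
}

#' Write a simulated pair to disk
#'
#' Writes `unfiltered.mrc`, `filtered.mrc`, the ground-truth table
#' `truth.csv` and a `scene.cfg` key/value file into a directory.
#'
#' @param sim Result of [simulate_pair()].
#' @param dir Output directory (created if needed).
#' @param scene The originating [synthetic_scene()] (for the config).
#' @return `dir`, invisibly.
#' @export
save_simulation <- function(sim, dir, scene = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(sim$pair$unfiltered, file.path(dir, "unfiltered.mrc"))
  write_image(sim$pair$filtered, file.path(dir, "filtered.mrc"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(scene)) {
    l <- scene$lattice
    lines <- c(
      sprintf("image_shape = %d %d", scene$image_shape[1L],
              scene$image_shape[2L]),
      sprintf("pixel_size_a = %.10g", scene$pixel_size_a),
      sprintf("spacing_um = %.10g", l$spacing_um),
      sprintf("hole_radius_px = %.10g", l$hole_radius_px),
      sprintf("scale_nm = %.10g", scene$profile$scale_nm),
      sprintf("vacuum_offset_nm = %.10g", scene$vacuum_offset_nm),
      sprintf("film_transmission = %.10g", scene$film_transmission),
      sprintf("hole_open_vacuum_factor = %.10g",
              scene$hole_open_vacuum_factor),
      sprintf("incident_rate = %.10g", scene$incident_rate),
      sprintf("exposure_s = %.10g", scene$exposure_s),
      sprintf("filtered_shift_px = %.10g %.10g",
              scene$filtered_shift_px[1L], scene$filtered_shift_px[2L]),
      sprintf("noise = %s", scene$noise),
      sprintf("seed = %s", format(scene$seed))
    )
    writeLines(lines, file.path(dir, "scene.cfg"))
  }
  invisible(dir)
}
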