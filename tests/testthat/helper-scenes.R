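# Shared fixtures, all generated in code.

PROF_200M <- default_profile(200, "M_SA", "FILTER")

# Compact grid-square scene: 256 px, 24 px hole pitch, 6 px hole radius
# (the geometry is scaled down from a survey acquisition so whole-scene
# tests stay fast; counting statistics are set per test).
tiny_scene <- function(thickness_field = 30, noise = FALSE, seed = 1L,
                       shape = c(256L, 256L), spacing_px = 24,
                       radius_px = 6, angle = 0, shift = c(0, 0),
                       profile = PROF_200M,
                       vacuum_offset_nm = profile$correction_nm, ...) {
  ps <- 144.6
  synthetic_scene(
    image_shape = shape, pixel_size_a = ps,
    spacing_um = spacing_px * ps * 1e-4,
    hole_radius_um = radius_px * ps * 1e-4,
    lattice_angle_deg = angle,
    thickness_field = thickness_field,
    profile = profile, vacuum_offset_nm = vacuum_offset_nm,
    filtered_shift_px = shift, noise = noise, seed = seed, ...
  )
}

# A smooth band-limited test image (for sub-pixel registration tests).
smooth_random_plane <- function(n = 128L, seed = 1L, smooth_px = 6) {
  z <- with_seed_test(seed, matrix(rnorm(n * n), n, n))
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  g <- exp(-2 * (pi * smooth_px * f)^2)
  k <- outer(g, g)
  zs <- Re(fft(fft(z) * k, inverse = TRUE)) / length(z)
  100 + 10 * zs / sd(zs)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Exact translation by an FFT phase ramp (band-limited construction,
# independent of the package's bilinear resampler).
fft_translate <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ky <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  kx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  if (nr %% 2 == 0) ky[nr %/% 2 + 1] <- 0  # drop the ambiguous Nyquist bin
  if (nc %% 2 == 0) kx[nc %/% 2 + 1] <- 0
  ramp <- exp(-2i * pi * (outer(ky, rep(1, nc)) * dy / nr +
                            outer(rep(1, nr), kx) * dx / nc))
  Re(fft(fft(m) * ramp, inverse = TRUE)) / length(m)
}

# Match detected holes to truth rows by nearest centre; returns the
# truth index per hole.
match_truth <- function(holes, truth) {
  vapply(seq_len(nrow(holes)), function(k) {
    which.min((truth$row_px - holes$row_px[k])^2 +
                (truth$col_px - holes$col_px[k])^2)
  }, integer(1L))
}

make_plane <- function(m, ps = 100, exposure = 1, slit = FALSE) {
  image_plane(m, pixel_size_a = ps, exposure_s = exposure,
              slit_inserted = slit)
}
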