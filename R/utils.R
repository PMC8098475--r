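# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers/tests can match on the error code rather
# than on message wording.
ice_stop <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(code, "icethick_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ice_warn <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(code, "icethick_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
  invisible(NULL)
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Circular shift of a matrix: content moves down by dy rows and right by
# dx cols (integer shifts only).
roll_matrix <- function(m, dy, dx) {
  nr <- nrow(m)
  nc <- ncol(m)
  dy <- ((dy %% nr) + nr) %% nr
  dx <- ((dx %% nc) + nc) %% nc
  ri <- ((seq_len(nr) - 1L - dy) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - dx) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

# Bilinear translation with circular boundary: content moves by (dy, dx),
# fractional shifts interpolate between the four neighbouring rolls.
translate_bilinear <- function(m, dy, dx) {
  iy <- floor(dy); fy <- dy - iy
  ix <- floor(dx); fx <- dx - ix
  if (fy == 0 && fx == 0) {
    return(roll_matrix(m, iy, ix))
  }
  m00 <- roll_matrix(m, iy, ix)
  m10 <- roll_matrix(m, iy + 1, ix)
  m01 <- roll_matrix(m, iy, ix + 1)
  m11 <- roll_matrix(m, iy + 1, ix + 1)
  (1 - fy) * (1 - fx) * m00 + fy * (1 - fx) * m10 +
    (1 - fy) * fx * m01 + fy * fx * m11
}

# Circular cross-correlation of image with a small centred kernel via FFT.
# Kernel centre (its [cy, cx] element) sits at lag zero, i.e. result[i, j]
# = sum_k kernel[k] * image[(i, j) + offset(k)].
circ_xcorr <- function(image, kernel) {
  nr <- nrow(image)
  nc <- ncol(image)
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  cy <- (kr + 1L) %/% 2L
  cx <- (kc + 1L) %/% 2L
  kp <- matrix(0, nr, nc)
  kp[seq_len(kr), seq_len(kc)] <- kernel
  kp <- roll_matrix(kp, -(cy - 1L), -(cx - 1L))
  out <- fft(fft(image) * Conj(fft(kp)), inverse = TRUE)
  Re(out) / length(out)
}
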