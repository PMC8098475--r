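#' Thickness from a zero-loss filtered / unfiltered intensity pair
#'
#' Implements the energy-filter relation
#' `D = lambda_inel * ln(I / I_zl) - C`:
#' the fraction of electrons removed by the zero-loss slit grows with the
#' amount of inelastic scattering, hence with thickness, and the
#' correction term `C` zeroes the apparent thickness measured over vacuum
#' in an empty hole.
#'
#' @param intensity_unfiltered Mean counts `I` without the slit (> 0).
#'   Vectorized.
#' @param intensity_filtered Mean counts `I_zl` with the slit inserted
#'   (> 0). Vectorized.
#' @param profile A FILTER-method [calibration_profile()].
#' @param clamp If `TRUE`, negative thicknesses are mapped to 0 (display
#'   and selection); the default `FALSE` returns the raw value so that
#'   calibration statistics stay unbiased.
#' @return Thickness in nm, same length as the inputs.
#' @examples
#' p <- default_profile(200, "M_SA", "FILTER")
#' thickness_filter(exp(1), 1, p)  # 305 * 1 - 4 = 301 nm
#' @export
thickness_filter <- function(intensity_unfiltered, intensity_filtered,
                             profile, clamp = FALSE) {
  stopifnot(inherits(profile, "calibration_profile"))
  if (profile$method != "FILTER") {
    ice_stop("method_mismatch",
             "thickness_filter() needs a FILTER profile, got %s", profile$method)
  }
  if (any(!is.finite(intensity_unfiltered)) || any(intensity_unfiltered <= 0) ||
      any(!is.finite(intensity_filtered)) || any(intensity_filtered <= 0)) {
    ice_stop("invalid_measurement", "intensities must be finite and > 0")
  }
  d <- profile$scale_nm * log(intensity_unfiltered / intensity_filtered) -
    profile$correction_nm
  if (clamp) d <- pmax(d, 0)
  d
}

#' Thickness by aperture-limited scattering (ALS)
#'
#' Implements `D = lambda_ALS * ln(I0 / I)`: the objective aperture
#' removes part of the elastically scattered electrons, so intensity
#' relative to a vacuum reference `I0` decays with thickness.  Used when
#' no energy filter is available.
#'
#' @param intensity Mean counts `I` over the measured area (> 0).
#'   Vectorized.
#' @param reference A [vacuum_reference()] holding `I0`.
#' @param profile An ALS-method [calibration_profile()].
#' @return Thickness in nm.  Values are negative when `I > I0` (brighter
#'   than the reference); these are returned raw with a warning.
#' @export
thickness_als <- function(intensity, reference, profile) {
  stopifnot(inherits(profile, "calibration_profile"),
            inherits(reference, "vacuum_reference"))
  if (profile$method != "ALS") {
    ice_stop("method_mismatch",
             "thickness_als() needs an ALS profile, got %s", profile$method)
  }
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    ice_stop("invalid_measurement", "intensity must be finite and > 0")
  }
  d <- profile$scale_nm * log(reference$intensity / intensity)
  if (any(d < 0)) {
    ice_warn("negative_thickness",
             "%d measurement(s) brighter than the vacuum reference (negative thickness)",
             sum(d < 0))
  }
  d
}

#' Fit the empty-hole correction term C
#'
#' Empty holes measured with the filter method read a consistent nonzero
#' apparent thickness; `C` is defined operationally as the offset that
#' brings them back to zero: `C = scale_nm * mean(log_attenuation)` over
#' vacuum samples, floored at 0.
#'
#' @param vacuum_samples A [calibration_samples()] table (only rows with
#'   `is_vacuum = TRUE` are used).
#' @param scale_nm The scaling constant (lambda) in nm.
#' @return Correction term in nm.
#' @export
fit_correction_term <- function(vacuum_samples, scale_nm) {
  stopifnot(inherits(vacuum_samples, "calibration_samples"))
  if (!is_number(scale_nm) || scale_nm <= 0) {
    ice_stop("domain_error", "scale_nm must be > 0")
  }
  vac <- vacuum_samples[vacuum_samples$is_vacuum, , drop = FALSE]
  if (nrow(vac) == 0L) {
    ice_stop("insufficient_data",
             "no vacuum samples (is_vacuum = TRUE) to fit the correction term")
  }
  c_nm <- scale_nm * mean(vac$log_attenuation)
  if (c_nm < 0) {
    ice_warn("data_quality",
             "fitted correction term is negative (%.3g nm); floored at 0 - check the vacuum measurements",
             c_nm)
    c_nm <- 0
  }
  c_nm
}

# Shared constructor for the classed fit objects returned by the lambda
# estimators: a one-parameter least-squares model in the classic R
# modelling idiom (coef/summary/predict/residuals all work).
new_lambda_fit <- function(scale_nm, se, correction_nm, x, y, fitted,
                           method, label) {
  structure(
    list(coefficients = c(scale_nm = scale_nm, correction_nm = correction_nm),
         se = c(scale_nm = se),
         residuals = y - fitted,
         fitted.values = fitted,
         log_attenuation = x,
         n = length(x),
         method = method,
         label = label),
    class = "lambda_fit"
  )
}

# Through-origin least squares y = lambda * x with standard error.
fit_through_origin <- function(x, y) {
  sxx <- sum(x^2)
  lambda <- sum(x * y) / sxx
  resid <- y - lambda * x
  dfree <- length(x) - 1L
  se <- if (dfree > 0) sqrt(sum(resid^2) / dfree / sxx) else NA_real_
  list(lambda = lambda, se = se)
}

#' Fit the apparent mean free path from calibrated thicknesses
#'
#' Estimates the scaling constant lambda of the filter method by least
#' squares on `true_D = lambda * log_attenuation - C`.  The default is
#' the two-step procedure: `C` is fixed first (taken from the vacuum
#' holes via [fit_correction_term()], or supplied), then lambda is the
#' through-origin regression of `true_D + C` on the log-attenuation.
#' With `joint = TRUE` both lambda and `C` are fitted together by
#' ordinary least squares.
#'
#' @param samples A [calibration_samples()] table: log-attenuations paired
#'   with true thicknesses from a reference method (e.g. tomography).
#' @param correction_nm The correction term to hold fixed.  When `NULL`,
#'   it is derived from the vacuum rows: with vacuum log-attenuation
#'   `m = mean(log_attenuation | vacuum)`, the model becomes
#'   `true_D = lambda * (log_attenuation - m)` and `C = lambda * m`.
#' @param joint Fit lambda and C jointly instead (two-parameter OLS).
#' @return An object of class `lambda_fit`; `coef()` gives `scale_nm`
#'   and `correction_nm`, `summary()` adds standard errors.
#' @export
fit_lambda_filter <- function(samples, correction_nm = NULL, joint = FALSE) {
  stopifnot(inherits(samples, "calibration_samples"))
  ice <- samples[!samples$is_vacuum, , drop = FALSE]
  if (nrow(ice) == 0L) {
    ice_stop("insufficient_data", "no non-vacuum calibration samples")
  }
  x_raw <- ice$log_attenuation
  y <- ice$true_thickness_nm
  if (joint) {
    if (nrow(ice) < 2L || stats::var(x_raw) == 0) {
      ice_stop("insufficient_data",
               "joint fit needs >= 2 samples with distinct log_attenuation")
    }
    fit <- stats::lm(y ~ x_raw)
    lambda <- unname(stats::coef(fit)[2L])
    c_nm <- -unname(stats::coef(fit)[1L])
    se <- suppressWarnings(summary(fit)$coefficients[2L, 2L])
    if (c_nm < 0) {
      ice_warn("data_quality",
               "jointly fitted correction term is negative (%.3g nm); floored at 0", c_nm)
      c_nm <- 0
    }
    return(new_lambda_fit(lambda, se, c_nm, x_raw, y,
                          lambda * x_raw - c_nm, "FILTER", "joint OLS"))
  }
  if (is.null(correction_nm)) {
    vac <- samples[samples$is_vacuum, , drop = FALSE]
    if (nrow(vac) > 0L) {
      m <- mean(vac$log_attenuation)
      x <- x_raw - m
      if (sum(x^2) == 0) {
        ice_stop("insufficient_data",
                 "log_attenuations indistinguishable from the vacuum level")
      }
      ft <- fit_through_origin(x, y)
      c_nm <- max(ft$lambda * m, 0)
      return(new_lambda_fit(ft$lambda, ft$se, c_nm, x_raw, y,
                            ft$lambda * x_raw - c_nm, "FILTER",
                            "two-step (C from vacuum holes)"))
    }
    correction_nm <- 0
  }
  x <- x_raw
  if (sum(x^2) == 0) {
    ice_stop("insufficient_data", "all log_attenuations are zero")
  }
  ft <- fit_through_origin(x, y + correction_nm)
  new_lambda_fit(ft$lambda, ft$se, correction_nm, x, y,
                 ft$lambda * x - correction_nm, "FILTER", "two-step (C fixed)")
}

#' Transfer a calibration across magnification regimes
#'
#' Calibrates lambda for a target regime (typically LM) from thicknesses
#' already measured on the *same holes* in a calibrated regime (typically
#' M/SA): least-squares fit of
#' `reference_D = lambda_target * log_attenuation - C_target` with
#' `C_target` held fixed.
#'
#' @param reference_thicknesses Per-hole thicknesses (nm) from the
#'   calibrated regime.
#' @param target_log_attenuations Per-hole log-attenuations measured in
#'   the target regime.  If both vectors are named, they are matched by
#'   name; otherwise they must be equal-length and in the same hole order.
#' @param target_correction_nm Correction term of the target regime, nm.
#' @return A `lambda_fit`.
#' @export
transfer_lambda_cross_regime <- function(reference_thicknesses,
                                         target_log_attenuations,
                                         target_correction_nm = 0) {
  d <- reference_thicknesses
  x <- target_log_attenuations
  if (!is.null(names(d)) && !is.null(names(x))) {
    if (!setequal(names(d), names(x))) {
      ice_stop("pairing_error",
               "hole ids differ between regimes: %s",
               paste(union(setdiff(names(d), names(x)),
                           setdiff(names(x), names(d))), collapse = ", "))
    }
    x <- x[names(d)]
  } else if (length(d) != length(x)) {
    ice_stop("pairing_error",
             "per-hole vectors have different lengths (%d vs %d)",
             length(d), length(x))
  }
  if (length(d) < 2L) {
    ice_stop("pairing_error", "cross-regime transfer needs >= 2 matched holes")
  }
  if (sum(x^2) == 0) {
    ice_stop("insufficient_data", "all target log_attenuations are zero")
  }
  ft <- fit_through_origin(x, d + target_correction_nm)
  new_lambda_fit(ft$lambda, ft$se, target_correction_nm, unname(x), unname(d),
                 ft$lambda * unname(x) - target_correction_nm, "FILTER",
                 "cross-regime transfer")
}

#' Calibrate the ALS coefficient against the filter method
#'
#' For the same holes, regresses filter-method thicknesses on ALS
#' log-attenuations through the origin:
#' `lambda_ALS = sum(D * lnr) / sum(lnr^2)`.
#'
#' @param filter_thicknesses Per-hole thicknesses (nm) from the filter
#'   method.
#' @param als_log_attenuations Per-hole `ln(I0/I)` from the ALS images.
#'   Name-matched like [transfer_lambda_cross_regime()].
#' @return A `lambda_fit` with `correction_nm = 0`.
#' @export
fit_lambda_als <- function(filter_thicknesses, als_log_attenuations) {
  d <- filter_thicknesses
  x <- als_log_attenuations
  if (!is.null(names(d)) && !is.null(names(x))) {
    if (!setequal(names(d), names(x))) {
      ice_stop("pairing_error", "hole ids differ between methods")
    }
    x <- x[names(d)]
  } else if (length(d) != length(x)) {
    ice_stop("pairing_error",
             "per-hole vectors have different lengths (%d vs %d)",
             length(d), length(x))
  }
  if (!any(x > 0)) {
    ice_stop("insufficient_data",
             "no positive ALS log_attenuations; cannot calibrate lambda_ALS")
  }
  ft <- fit_through_origin(x, d)
  new_lambda_fit(ft$lambda, ft$se, 0, unname(x), unname(d),
                 ft$lambda * unname(x), "ALS", "ALS vs filter comparison")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("<lambda_fit> %s (%s)\n", x$label, x$method))
  cat(sprintf("  scale_nm:      %.4g", x$coefficients[["scale_nm"]]))
  if (is.finite(x$se[["scale_nm"]])) {
    cat(sprintf("  (SE %.3g)", x$se[["scale_nm"]]))
  }
  cat("\n")
  cat(sprintf("  correction_nm: %.4g\n", x$coefficients[["correction_nm"]]))
  cat(sprintf("  n = %d samples, residual RMS %.3g nm\n",
              x$n, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.lambda_fit <- function(object, ...) object$coefficients

#' @export
residuals.lambda_fit <- function(object, ...) object$residuals

#' @export
summary.lambda_fit <- function(object, ...) {
  out <- list(
    label = object$label,
    method = object$method,
    coefficients = object$coefficients,
    se = object$se,
    n = object$n,
    sigma = sqrt(sum(object$residuals^2) / max(object$n - 1L, 1L))
  )
  class(out) <- "summary.lambda_fit"
  out
}

#' @export
print.summary.lambda_fit <- function(x, ...) {
  cat(sprintf("Calibration fit: %s (%s method), n = %d\n",
              x$label, x$method, x$n))
  cat(sprintf("  scale_nm      %.6g  SE %.4g\n",
              x$coefficients[["scale_nm"]], x$se[["scale_nm"]]))
  cat(sprintf("  correction_nm %.6g (held fixed unless jointly fitted)\n",
              x$coefficients[["correction_nm"]]))
  cat(sprintf("  residual sigma %.4g nm\n", x$sigma))
  invisible(x)
}

#' Predict thickness from log-attenuation with a fitted calibration
#'
#' @param object A `lambda_fit`.
#' @param log_attenuation New log-attenuation values; defaults to the
#'   training values.
#' @param ... Unused.
#' @return Thicknesses in nm.
#' @export
predict.lambda_fit <- function(object, log_attenuation = NULL, ...) {
  x <- log_attenuation %||% object$log_attenuation
  object$coefficients[["scale_nm"]] * x -
    object$coefficients[["correction_nm"]]
}

#' Convert a lambda fit into a calibration profile
#'
#' @param fit A `lambda_fit`.
#' @inheritParams calibration_profile
#' @return A [calibration_profile()].
#' @export
as_profile <- function(fit, voltage_kv, regime, source = NULL) {
  stopifnot(inherits(fit, "lambda_fit"))
  calibration_profile(voltage_kv, regime, fit$method,
                      fit$coefficients[["scale_nm"]],
                      fit$coefficients[["correction_nm"]],
                      source %||% fit$label)
}
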