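#' Calibration profile for thickness measurement
#'
#' A calibration profile bundles the scaling constant and the empty-hole
#' correction term used to convert log-attenuation into ice thickness.
#' For the energy-filter (zero-loss) method the scale is the apparent
#' inelastic mean free path and the correction term `C` zeroes
#' measurements over vacuum in an empty hole; for the aperture-limited
#' scattering (ALS) method the scale is the ALS coefficient and `C` is
#' identically zero.
#'
#' @param voltage_kv Acceleration voltage in kV (200 or 300).
#' @param regime Magnification regime: `"M_SA"` (medium / selected-area)
#'   or `"LM"` (low magnification).
#' @param method `"FILTER"` (zero-loss energy filter) or `"ALS"`.
#' @param scale_nm Scaling constant in nm (lambda_inel or lambda_ALS).
#' @param correction_nm Correction term C in nm; must be 0 for ALS.
#' @param source Free-text provenance (instrument, date, calibration run).
#'
#' @return An object of class `calibration_profile`.
#' @seealso [default_profile()] for the built-in constants,
#'   [thickness_filter()], [thickness_als()].
#' @export
calibration_profile <- function(voltage_kv, regime, method, scale_nm,
                                correction_nm = 0, source = "") {
  regime <- match.arg(regime, c("M_SA", "LM"))
  method <- match.arg(method, c("FILTER", "ALS"))
  if (!is_count(voltage_kv) || !(voltage_kv %in% c(200, 300))) {
    ice_stop("domain_error", "voltage_kv must be 200 or 300, got %s",
             paste(voltage_kv, collapse = ","))
  }
  if (!is_number(scale_nm) || scale_nm <= 0) {
    ice_stop("domain_error", "scale_nm must be a positive length in nm")
  }
  if (!is_number(correction_nm) || correction_nm < 0) {
    ice_stop("domain_error", "correction_nm must be >= 0 nm")
  }
  if (method == "ALS" && correction_nm != 0) {
    ice_stop("domain_error",
             "ALS profiles have no correction term (correction_nm must be 0)")
  }
  structure(
    list(voltage_kv = as.integer(voltage_kv), regime = regime,
         method = method, scale_nm = as.numeric(scale_nm),
         correction_nm = as.numeric(correction_nm),
         source = as.character(source)),
    class = "calibration_profile"
  )
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("<calibration_profile> %d kV / %s / %s\n",
              x$voltage_kv, x$regime, x$method))
  cat(sprintf("  scale:      %g nm (%s)\n", x$scale_nm,
              if (x$method == "FILTER") "lambda_inel" else "lambda_ALS"))
  cat(sprintf("  correction: %g nm\n", x$correction_nm))
  if (nzchar(x$source)) cat(sprintf("  source:     %s\n", x$source))
  invisible(x)
}

# Built-in registry of published calibration constants, keyed by
# voltage / regime / method.
.profile_registry <- function() {
  data.frame(
    voltage_kv = c(200L, 200L, 300L, 300L, 200L, 300L),
    regime = c("M_SA", "LM", "M_SA", "LM", "LM", "LM"),
    method = c("FILTER", "FILTER", "FILTER", "FILTER", "ALS", "ALS"),
    scale_nm = c(305, 485, 435, 805, 600, 1750),
    correction_nm = c(4, 35, 1, 65, 0, 0),
    source = c(
      "Talos Arctica 200 kV, BioQuantum/K2, tomogram calibration",
      "Talos Arctica 200 kV, LM, cross-magnification transfer",
      "Titan Krios 300 kV, SA, literature value",
      "Titan Krios 300 kV, LM, cross-magnification transfer",
      "Talos Arctica 200 kV, ALS vs filter comparison",
      "Titan Krios 300 kV, ALS vs filter comparison"
    ),
    stringsAsFactors = FALSE
  )
}

#' Built-in calibration constants
#'
#' Looks up the default calibration profile for a microscope voltage,
#' magnification regime and measurement method.  The registry holds the
#' apparent inelastic mean free paths 305 nm (200 kV, M/SA), 485 nm
#' (200 kV, LM), 435 nm (300 kV, M/SA) and 805 nm (300 kV, LM) with
#' correction terms 4, 35, 1 and 65 nm respectively, and the ALS
#' coefficients 600 nm (200 kV, LM) and 1750 nm (300 kV, LM).  These are
#' apparent, instrument-specific values, not physical constants, and
#' should be recalibrated after any major change of configuration (see
#' [fit_lambda_filter()] and friends).
#'
#' @inheritParams calibration_profile
#' @return A [calibration_profile()].
#' @examples
#' default_profile(200, "M_SA", "FILTER")
#' default_profile(300, "LM", "ALS")
#' @export
default_profile <- function(voltage_kv, regime = c("M_SA", "LM"),
                            method = c("FILTER", "ALS")) {
  regime <- match.arg(regime)
  method <- match.arg(method)
  reg <- .profile_registry()
  hit <- reg$voltage_kv == voltage_kv & reg$regime == regime &
    reg$method == method
  if (!any(hit)) {
    ice_stop("no_default_calibration",
             "no default calibration for (%s kV, %s, %s)",
             paste(voltage_kv, collapse = ","), regime, method)
  }
  row <- reg[which(hit)[1L], ]
  calibration_profile(row$voltage_kv, row$regime, row$method,
                      row$scale_nm, row$correction_nm, row$source)
}

#' Vacuum reference intensity for the ALS method
#'
#' The ALS method compares the observed intensity with a reference
#' intensity `I0` measured over vacuum *inside an empty hole* (not over a
#' broken film: empty holes read systematically brighter than open
#' vacuum, so the reference must be taken under the same optical
#' conditions as the measurements).
#'
#' @param intensity Mean counts per pixel over vacuum inside an empty hole.
#' @param settings_tag Free text identifying the imaging preset.
#' @return An object of class `vacuum_reference`.
#' @export
vacuum_reference <- function(intensity, settings_tag = "") {
  if (!is_number(intensity) || intensity <= 0) {
    ice_stop("invalid_measurement", "vacuum reference intensity must be > 0")
  }
  structure(list(intensity = as.numeric(intensity),
                 settings_tag = as.character(settings_tag)),
            class = "vacuum_reference")
}

#' Camera profile: counting conversion and coincidence-loss ceiling
#'
#' Electron-counting cameras report either electrons or counts per pixel;
#' the two differ by a detector-dependent conversion factor, and counting
#' becomes non-linear (coincidence loss) above a per-pixel rate ceiling.
#' The K2 default conversion is 10.7/12.9 counts per electron with a
#' 10 counts/px/s ceiling.  The K3 counts close to one count per electron
#' at roughly four times the K2 frame rate; both values are calibration
#' knobs, not constants.
#'
#' @param model `"K2"`, `"K3"` or `"GENERIC"`.
#' @param counts_per_electron Conversion factor; defaults by model.
#' @param max_count_rate Coincidence-loss ceiling in counts/px/s.
#' @return An object of class `camera_profile`.
#' @export
camera_profile <- function(model = c("K2", "K3", "GENERIC"),
                           counts_per_electron = NULL,
                           max_count_rate = NULL) {
  model <- match.arg(model)
  defaults <- switch(model,
    K2 = list(cpe = 10.7 / 12.9, max = 10),
    K3 = list(cpe = 1.0, max = 40),
    GENERIC = list(cpe = 1.0, max = 10)
  )
  cpe <- counts_per_electron %||% defaults$cpe
  mcr <- max_count_rate %||% defaults$max
  if (!is_number(cpe) || cpe <= 0) {
    ice_stop("domain_error", "counts_per_electron must be > 0")
  }
  if (!is_number(mcr) || mcr <= 0) {
    ice_stop("domain_error", "max_count_rate must be > 0")
  }
  structure(list(model = model, counts_per_electron = cpe,
                 max_count_rate = mcr),
            class = "camera_profile")
}

#' Convert an electron flux to a camera count rate
#'
#' @param flux Electrons per pixel per second (>= 0).
#' @param camera A [camera_profile()].
#' @return Counts per pixel per second.
#' @examples
#' counts_from_flux(12.9, camera_profile("K2"))  # 10.7
#' @export
counts_from_flux <- function(flux, camera = camera_profile("K2")) {
  stopifnot(inherits(camera, "camera_profile"))
  if (!is.numeric(flux) || any(!is.finite(flux)) || any(flux < 0)) {
    ice_stop("domain_error", "flux must be >= 0 electrons/px/s")
  }
  flux * camera$counts_per_electron
}

#' Coincidence-loss guard on the mean count rate
#'
#' Checks the mean per-pixel count rate against the camera's
#' coincidence-loss ceiling.  Rates at or below the ceiling pass; higher
#' rates produce a `"warn"` verdict (and an R warning) but never abort
#' processing, since the measurement is still usable, just potentially
#' biased by undercounting.
#'
#' @param mean_rate Mean counts per pixel per second (>= 0).
#' @param camera A [camera_profile()].
#' @return A list with elements `verdict` (`"pass"` or `"warn"`),
#'   `rate` and `ceiling`.
#' @export
check_count_rate <- function(mean_rate, camera = camera_profile("K2")) {
  stopifnot(inherits(camera, "camera_profile"))
  if (!is_number(mean_rate) || mean_rate < 0) {
    ice_stop("domain_error", "mean_rate must be >= 0")
  }
  verdict <- if (mean_rate <= camera$max_count_rate) "pass" else "warn"
  if (verdict == "warn") {
    ice_warn("count_rate_guard",
             "mean count rate %.3g counts/px/s exceeds the %s ceiling of %.3g; coincidence loss likely",
             mean_rate, camera$model, camera$max_count_rate)
  }
  list(verdict = verdict, rate = mean_rate, ceiling = camera$max_count_rate)
}

#' Calibration sample table
#'
#' One row per measured position: the log-attenuation (`ln(I/I_zl)` for
#' the filter method, `ln(I0/I)` for ALS) together with an independently
#' determined true thickness (for example from a tomogram cross-section).
#' Vacuum rows (`is_vacuum = TRUE`) have true thickness 0 and anchor the
#' correction term.
#'
#' @param log_attenuation Dimensionless log intensity ratios.
#' @param true_thickness_nm True thicknesses in nm (>= 0).
#' @param is_vacuum Logical; vacuum (empty-hole) rows.
#' @param hole_id Optional integer ids; defaults to the row number.
#' @return A `data.frame` of class `calibration_samples`.
#' @export
calibration_samples <- function(log_attenuation, true_thickness_nm,
                                is_vacuum = FALSE, hole_id = NULL) {
  n <- length(log_attenuation)
  is_vacuum <- rep_len(as.logical(is_vacuum), n)
  true_thickness_nm <- rep_len(as.numeric(true_thickness_nm), n)
  hole_id <- hole_id %||% seq_len(n)
  if (any(!is.finite(log_attenuation))) {
    ice_stop("domain_error", "log_attenuation must be finite")
  }
  if (any(!is.finite(true_thickness_nm)) || any(true_thickness_nm < 0)) {
    ice_stop("domain_error", "true_thickness_nm must be finite and >= 0")
  }
  if (any(is_vacuum & true_thickness_nm != 0)) {
    ice_stop("domain_error", "vacuum samples must have true_thickness_nm = 0")
  }
  structure(
    data.frame(hole_id = as.integer(hole_id),
               log_attenuation = as.numeric(log_attenuation),
               true_thickness_nm = true_thickness_nm,
               is_vacuum = is_vacuum),
    class = c("calibration_samples", "data.frame")
  )
}

#' Read / write calibration sample tables as CSV
#'
#' Files carry the columns `hole_id`, `log_attenuation`,
#' `true_thickness_nm`, `is_vacuum`.
#'
#' @param path File path.
#' @return `read_calibration_csv()` returns a [calibration_samples()]
#'   table; `write_calibration_csv()` returns `path` invisibly.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) {
    ice_stop("parse_error", "calibration file not found: %s", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hole_id", "log_attenuation", "true_thickness_nm", "is_vacuum")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    ice_stop("parse_error", "calibration CSV %s is missing column(s): %s",
             path, paste(missing, collapse = ", "))
  }
  calibration_samples(df$log_attenuation, df$true_thickness_nm,
                      as.logical(df$is_vacuum), df$hole_id)
}

#' @rdname read_calibration_csv
#' @param samples A [calibration_samples()] table.
#' @export
write_calibration_csv <- function(samples, path) {
  stopifnot(inherits(samples, "calibration_samples"))
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a set of calibration profiles to a config file
#'
#' Profiles are written as one bracketed section per registry key
#' (`[voltage/regime/method]`) with `key = value` lines, a format both
#' humans and the package can read back.
#'
#' @param profiles A list of [calibration_profile()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_registry <- function(profiles, path) {
  if (inherits(profiles, "calibration_profile")) profiles <- list(profiles)
  lines <- character(0)
  for (p in profiles) {
    stopifnot(inherits(p, "calibration_profile"))
    lines <- c(lines,
               sprintf("[%d/%s/%s]", p$voltage_kv, p$regime, p$method),
               sprintf("scale_nm = %.10g", p$scale_nm),
               sprintf("correction_nm = %.10g", p$correction_nm),
               sprintf("source = %s", p$source),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_profile_registry
#' @return `read_profile_registry()` returns a named list of profiles,
#'   keyed `"voltage/regime/method"`.
#' @export
read_profile_registry <- function(path) {
  if (!file.exists(path)) {
    ice_stop("parse_error", "profile registry not found: %s", path)
  }
  lines <- trimws(readLines(path))
  profiles <- list()
  key <- NULL
  fields <- list()
  flush <- function() {
    if (is.null(key)) return()
    parts <- strsplit(key, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) {
      ice_stop("parse_error", "bad registry section [%s]", key)
    }
    p <- calibration_profile(as.integer(parts[1L]), parts[2L], parts[3L],
                             as.numeric(fields$scale_nm),
                             as.numeric(fields$correction_nm %||% 0),
                             fields$source %||% "")
    profiles[[key]] <<- p
  }
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      flush()
      key <- sub("^\\[(.*)\\]$", "\\1", ln)
      fields <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      fields[[trimws(kv[1L])]] <- trimws(paste(kv[-1L], collapse = "="))
    }
  }
  flush()
  profiles
}
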