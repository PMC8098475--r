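# End-to-end workflow: measure -> detect -> select -> group -> export.

#' Configuration for the targeting pipeline
#'
#' Collects all the knobs of [run_pipeline()].  Input is either a scene
#' (simulation) or a pair of MRC paths (unfiltered / filtered).
#'
#' @param input_unfiltered,input_filtered MRC paths of the image pair, or
#'   `NULL` when a `scene` is given.
#' @param scene A [synthetic_scene()] to simulate instead of reading.
#' @param output_dir Directory for exported artefacts.
#' @param voltage_kv,regime,method Calibration registry key for the
#'   measurement profile.
#' @param profile Explicit [calibration_profile()] override.
#' @param camera A [camera_profile()] for the count-rate guard.
#' @param policy A [selection_policy()] (thickness window, nm).
#' @param bin_factor Binning applied before mapping (survey default 4).
#' @param apply_median,median_kernel Ratio-image median filtering.
#' @param radius_fraction Per-hole measurement radius fraction.
#' @param pattern Beam-image-shift grouping pattern `(rows, cols)`.
#' @param spacing_hint_um Known hole pitch in um (helps the lattice
#'   search); defaults to the scene's pitch when simulating.
#' @param palette Heatmap palette.
#' @param seed Seed forwarded to the scene when simulating.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_unfiltered = NULL, input_filtered = NULL,
                       scene = NULL, output_dir = tempfile("icethick_run_"),
                       voltage_kv = 200, regime = "M_SA", method = "FILTER",
                       profile = NULL, camera = camera_profile("K2"),
                       policy = selection_policy(20, 40),
                       bin_factor = 4L, apply_median = TRUE,
                       median_kernel = 3L, radius_fraction = 0.5,
                       pattern = c(3L, 3L), spacing_hint_um = NULL,
                       palette = "DM", seed = NULL) {
  if (is.null(scene) &&
      (is.null(input_unfiltered) || is.null(input_filtered))) {
    ice_stop("domain_error",
             "either a scene or both input MRC paths must be given")
  }
  profile <- profile %||% default_profile(voltage_kv, regime, method)
  structure(
    list(input_unfiltered = input_unfiltered,
         input_filtered = input_filtered, scene = scene,
         output_dir = output_dir, profile = profile, camera = camera,
         policy = policy, bin_factor = as.integer(bin_factor),
         apply_median = isTRUE(apply_median),
         median_kernel = as.integer(median_kernel),
         radius_fraction = radius_fraction,
         pattern = as.integer(pattern),
         spacing_hint_um = spacing_hint_um, palette = palette, seed = seed),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, icethick_error = function(e) {
    ice_stop(class(e)[1L], "[stage %s] %s", name, conditionMessage(e))
  })
}

#' Run the full thickness-based targeting pipeline
#'
#' Executes align -> map -> detect -> measure -> select -> group ->
#' export on a simulated scene or an MRC image pair, writing the hole
#' table (CSV), a Navigator autodoc, the thickness map (MRC + sidecar)
#' and a heatmap PNG into the output directory.
#'
#' @param config A [run_config()].
#' @return A `run_report`: hole/selection/group counts, the count-rate
#'   guard verdict, paths of the written artefacts, and the measured
#'   `hole_set` (attribute `holes`) for further work.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  report <- withCallingHandlers(icethick_warning = note, {
    truth <- NULL
    pair <- stage("input", {
      if (!is.null(config$scene)) {
        scn <- config$scene
        if (!is.null(config$seed)) scn$seed <- config$seed
        sim <- simulate_pair(scn)
        truth <- sim$truth
        if (is.null(config$spacing_hint_um)) {
          config$spacing_hint_um <- scn$lattice$spacing_um
        }
        sim$pair
      } else {
        image_pair(read_image(config$input_unfiltered, slit_inserted = FALSE),
                   read_image(config$input_filtered, slit_inserted = TRUE))
      }
    })
    pair <- stage("bin", {
      if (config$bin_factor > 1L) {
        image_pair(bin_image(pair$unfiltered, config$bin_factor),
                   bin_image(pair$filtered, config$bin_factor),
                   shift_px = pair$shift_px / config$bin_factor,
                   aligned = FALSE)
      } else {
        pair
      }
    })
    guard <- stage("guard", {
      check_count_rate(mean_count_rate(pair$unfiltered), config$camera)
    })
    pair <- stage("align", align_pair(pair))
    dmap <- stage("map", {
      thickness_map(pair, config$profile,
                    apply_median = config$apply_median,
                    median_kernel = config$median_kernel)
    })
    lattice <- stage("detect", {
      estimate_lattice(pair$unfiltered, config$spacing_hint_um)
    })
    holes <- stage("detect", detect_holes(pair$unfiltered, lattice))
    holes <- stage("measure", {
      measure_holes(holes, pair, config$profile,
                    radius_fraction = config$radius_fraction)
    })
    holes <- stage("select", select_holes(holes, config$policy))
    groups <- stage("group", group_holes(holes, config$pattern))
    holes <- attr(groups, "holes")

    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- stage("export", {
      p <- list(
        holes_csv = file.path(config$output_dir, "holes.csv"),
        navigator = file.path(config$output_dir, "targets.nav"),
        map_mrc = file.path(config$output_dir, "thickness.mrc"),
        heatmap = file.path(config$output_dir, "heatmap.png")
      )
      write_holes_csv(holes, p$holes_csv)
      export_navigator(holes, p$navigator, groups = groups,
                       policy = config$policy,
                       pixel_size_a = pair$unfiltered$pixel_size_a)
      write_thickness_map(dmap, p$map_mrc, policy = config$policy)
      write_heatmap_png(render_heatmap(dmap, config$policy,
                                       palette = config$palette,
                                       base = pair$unfiltered),
                        p$heatmap)
      if (!is.null(truth)) {
        p$truth_csv <- file.path(config$output_dir, "truth.csv")
        utils::write.csv(truth, p$truth_csv, row.names = FALSE)
      }
      p
    })
    structure(
      list(n_holes = nrow(holes), n_selected = sum(holes$selected),
           n_groups = length(groups),
           summary = attr(holes, "summary"),
           guard = guard, paths = paths, warnings = warnings_seen,
           shift_px = pair$shift_px),
      class = "run_report", holes = holes, groups = groups, truth = truth
    )
  })
  report$warnings <- warnings_seen
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  holes: %d detected, %d selected, %d group(s)\n",
              x$n_holes, x$n_selected, x$n_groups))
  s <- x$summary
  cat(sprintf("  window classes: below %d / within %d / above %d / flagged %d\n",
              s[["n_below"]], s[["n_within"]], s[["n_above"]],
              s[["n_flagged"]]))
  cat(sprintf("  count-rate guard: %s (%.3g counts/px/s, ceiling %.3g)\n",
              x$guard$verdict, x$guard$rate, x$guard$ceiling))
  cat(sprintf("  estimated pair shift: (%.2f, %.2f) px\n",
              x$shift_px[1L], x$shift_px[2L]))
  if (length(x$warnings)) {
    cat(sprintf("  warnings: %d\n", length(x$warnings)))
  }
  for (p in names(x$paths)) cat(sprintf("  %s: %s\n", p, x$paths[[p]]))
  invisible(x)
}

#' Fit calibration constants from a sample table on disk
#'
#' Reads a calibration CSV (columns `hole_id`, `log_attenuation`,
#' `true_thickness_nm`, `is_vacuum`) and dispatches to the requested
#' fitting procedure.
#'
#' @param samples_path CSV path.
#' @param mode `"lambda_filter"` (fit the mean free path, two-step C),
#'   `"correction"` (fit C for a given scale), `"lambda_als"` (ALS
#'   coefficient: `true_thickness_nm` is read as the filter-method
#'   thickness), or `"cross_regime"` (`true_thickness_nm` is read as the
#'   reference-regime thickness).
#' @param scale_nm Scale for `mode = "correction"`.
#' @param correction_nm Fixed correction for `"lambda_filter"` /
#'   `"cross_regime"`; when `NULL` for `"lambda_filter"`, C is derived
#'   from the vacuum rows.
#' @param voltage_kv,regime Registry key for the written profile.
#' @param out_registry Optional path: the fitted profile is appended to
#'   this profile-registry config file.
#' @return A `lambda_fit` (or, for `mode = "correction"`, a number) with
#'   the written profile as attribute `profile` where applicable.
#' @export
run_calibrate <- function(samples_path,
                          mode = c("lambda_filter", "correction",
                                   "lambda_als", "cross_regime"),
                          scale_nm = NULL, correction_nm = NULL,
                          voltage_kv = 200, regime = "M_SA",
                          out_registry = NULL) {
  mode <- match.arg(mode)
  samples <- read_calibration_csv(samples_path)
  result <- switch(mode,
    correction = {
      if (is.null(scale_nm)) {
        ice_stop("domain_error", "mode 'correction' needs scale_nm")
      }
      fit_correction_term(samples, scale_nm)
    },
    lambda_filter = fit_lambda_filter(samples, correction_nm = correction_nm),
    lambda_als = {
      ice <- samples[!samples$is_vacuum, , drop = FALSE]
      fit_lambda_als(ice$true_thickness_nm, ice$log_attenuation)
    },
    cross_regime = {
      ice <- samples[!samples$is_vacuum, , drop = FALSE]
      transfer_lambda_cross_regime(ice$true_thickness_nm,
                                   ice$log_attenuation,
                                   correction_nm %||% 0)
    }
  )
  if (inherits(result, "lambda_fit") && !is.null(out_registry)) {
    prof <- as_profile(result, voltage_kv, regime,
                       source = sprintf("fit from %s (%s)",
                                        basename(samples_path), mode))
    existing <- if (file.exists(out_registry)) {
      read_profile_registry(out_registry)
    } else {
      list()
    }
    existing[[sprintf("%d/%s/%s", prof$voltage_kv, prof$regime,
                      prof$method)]] <- prof
    write_profile_registry(existing, out_registry)
    attr(result, "profile") <- prof
  }
  result
}
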