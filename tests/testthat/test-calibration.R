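# Calibration constants, the two thickness relations, and the fitting
# procedures.

test_that("default_profile reproduces the published constant registry", {
  expected <- list(
    list(200, "M_SA", "FILTER", 305, 4),
    list(200, "LM", "FILTER", 485, 35),
    list(300, "M_SA", "FILTER", 435, 1),
    list(300, "LM", "FILTER", 805, 65),
    list(200, "LM", "ALS", 600, 0),
    list(300, "LM", "ALS", 1750, 0)
  )
  for (e in expected) {
    p <- default_profile(e[[1]], e[[2]], e[[3]])
    expect_equal(p$scale_nm, e[[4]])
    expect_equal(p$correction_nm, e[[5]])
  }
  expect_error(default_profile(120, "LM", "FILTER"),
               class = "no_default_calibration")
  expect_error(default_profile(200, "M_SA", "ALS"),
               class = "no_default_calibration")
})

test_that("ALS profiles cannot carry a correction term", {
  expect_error(calibration_profile(200, "LM", "ALS", 600, correction_nm = 5),
               class = "domain_error")
  expect_error(calibration_profile(200, "LM", "FILTER", -10),
               class = "domain_error")
})

test_that("thickness_filter implements D = lambda ln(I/Izl) - C", {
  p <- default_profile(200, "M_SA", "FILTER")
  expect_equal(thickness_filter(exp(1), 1, p), 301)
  p0 <- calibration_profile(200, "M_SA", "FILTER", 305, 0)
  expect_equal(thickness_filter(5, 5, p0), 0)
  # the vacuum-hole case the correction is defined to zero out
  expect_equal(thickness_filter(exp(4 / 305), 1, p), 0, tolerance = 1e-12)
  # clamping maps negative to 0 but the raw value stays obtainable
  expect_equal(thickness_filter(1, 1, p), -4)
  expect_equal(thickness_filter(1, 1, p, clamp = TRUE), 0)
  expect_error(thickness_filter(0, 1, p), class = "invalid_measurement")
  expect_error(thickness_filter(1, -2, p), class = "invalid_measurement")
  expect_error(thickness_filter(2, 1, default_profile(200, "LM", "ALS")),
               class = "method_mismatch")
})

test_that("thickness_filter round-trips any thickness through the forward law", {
  p <- default_profile(300, "LM", "FILTER")
  for (d in c(0, 0.5, 10, 33.3, 120, 900)) {
    izl <- 7.3
    i <- exp((d + p$correction_nm) / p$scale_nm) * izl
    expect_equal(thickness_filter(i, izl, p), d, tolerance = 1e-9)
  }
  # strictly increasing in the log ratio
  lnr <- seq(0.01, 0.5, length.out = 25)
  d <- thickness_filter(exp(lnr), 1, p)
  expect_true(all(diff(d) > 0))
})

test_that("thickness_als implements D = lambda ln(I0/I)", {
  ref <- vacuum_reference(10)
  p600 <- calibration_profile(200, "LM", "ALS", 600)
  p1750 <- calibration_profile(300, "LM", "ALS", 1750)
  expect_equal(thickness_als(10, ref, p600), 0)
  expect_equal(thickness_als(10 / exp(1), ref, p600), 600)
  expect_equal(thickness_als(10 / exp(0.05), ref, p1750), 87.5)
  # strictly decreasing in I
  d <- thickness_als(seq(2, 10, length.out = 20), ref, p600)
  expect_true(all(diff(d) < 0))
  # brighter than vacuum: raw negative value plus a warning
  expect_warning(dneg <- thickness_als(12, ref, p600),
                 class = "negative_thickness")
  expect_lt(dneg, 0)
  expect_error(thickness_als(0, ref, p600), class = "invalid_measurement")
  expect_error(thickness_als(5, ref, PROF_200M), class = "method_mismatch")
})

test_that("fit_correction_term is the vacuum-mean zero offset", {
  s <- calibration_samples(rep(0.0131, 4), 0, is_vacuum = TRUE)
  expect_equal(fit_correction_term(s, 305), 305 * 0.0131)
  expect_equal(fit_correction_term(s, 305), 4.0, tolerance = 0.01)
  s0 <- calibration_samples(rep(0, 3), 0, is_vacuum = TRUE)
  expect_equal(fit_correction_term(s0, 305), 0)
  # negative vacuum mean floors at zero with a data-quality warning
  sneg <- calibration_samples(c(-0.01, -0.02), 0, is_vacuum = TRUE)
  expect_warning(cneg <- fit_correction_term(sneg, 305),
                 class = "data_quality")
  expect_equal(cneg, 0)
  ice_only <- calibration_samples(c(0.1, 0.2), c(30, 60))
  expect_error(fit_correction_term(ice_only, 305),
               class = "insufficient_data")
  expect_error(fit_correction_term(s[0, ], 305),
               class = "insufficient_data")
})

test_that("vacuum correction then measurement zeroes empty holes", {
  # fit C from vacuum holes, then measure those same holes: mean 0
  lnr_vac <- c(0.0130, 0.0132, 0.0131)
  s <- calibration_samples(lnr_vac, 0, is_vacuum = TRUE)
  c_nm <- fit_correction_term(s, 305)
  p <- calibration_profile(200, "M_SA", "FILTER", 305, c_nm)
  d <- thickness_filter(exp(lnr_vac), 1, p)
  expect_equal(mean(d), 0, tolerance = 1e-12)
})

test_that("fit_lambda_filter recovers lambda exactly on noiseless data", {
  for (truth in list(c(305, 4), c(485, 35), c(435, 1), c(805, 65))) {
    lam <- truth[1]; cc <- truth[2]
    d <- seq(10, 100, length.out = 12)
    s <- calibration_samples((d + cc) / lam, d)
    fit <- fit_lambda_filter(s, correction_nm = cc)
    expect_equal(unname(coef(fit)["scale_nm"]), lam, tolerance = 1e-9)
  }
})

test_that("fit_lambda_filter matches the closed-form and lm() oracles on noisy data", {
  s <- simulate_calibration_set(485, 35, n_holes = 20, noise_sd_nm = 5,
                                seed = 42)
  fit <- fit_lambda_filter(s, correction_nm = 35)
  ice <- s[!s$is_vacuum, ]
  # closed-form through-origin regression of (D + C) on lnr
  oracle <- sum(ice$log_attenuation * (ice$true_thickness_nm + 35)) /
    sum(ice$log_attenuation^2)
  expect_equal(unname(coef(fit)["scale_nm"]), oracle, tolerance = 1e-12)
  # independent route: lm without intercept
  lmfit <- lm(I(true_thickness_nm + 35) ~ log_attenuation + 0, data = ice)
  expect_equal(unname(coef(fit)["scale_nm"]), unname(coef(lmfit)[1]),
               tolerance = 1e-10)
  expect_equal(unname(fit$se["scale_nm"]),
               summary(lmfit)$coefficients[1, 2], tolerance = 1e-8)
  expect_lt(abs(coef(fit)["scale_nm"] - 485) / 485, 0.02)
})

test_that("fit_lambda_filter solves the single-point case", {
  s <- calibration_samples((30 + 4) / 305, 30)
  fit <- fit_lambda_filter(s, correction_nm = 4)
  expect_equal(unname(coef(fit)["scale_nm"]), 305, tolerance = 1e-9)
  expect_true(is.na(fit$se["scale_nm"]))
})

test_that("fit_lambda_filter derives C from vacuum rows when not given", {
  s <- simulate_calibration_set(305, 4, n_holes = 25, noise_sd_nm = 0,
                                seed = 3)
  fit <- fit_lambda_filter(s)
  expect_equal(unname(coef(fit)["scale_nm"]), 305, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["correction_nm"]), 4, tolerance = 1e-6)
  # joint OLS route agrees on noiseless data
  jfit <- fit_lambda_filter(s, joint = TRUE)
  expect_equal(unname(coef(jfit)["scale_nm"]), 305, tolerance = 1e-6)
  expect_equal(unname(coef(jfit)["correction_nm"]), 4, tolerance = 1e-6)
})

test_that("fit_lambda_filter rejects degenerate inputs", {
  vac_only <- calibration_samples(rep(0.01, 3), 0, is_vacuum = TRUE)
  expect_error(fit_lambda_filter(vac_only, correction_nm = 4),
               class = "insufficient_data")
  zeros <- calibration_samples(rep(0, 3), c(10, 20, 30))
  expect_error(fit_lambda_filter(zeros, correction_nm = 0),
               class = "insufficient_data")
})

test_that("cross-regime transfer recovers the LM scale from M/SA thicknesses", {
  d_ref <- seq(15, 90, length.out = 10)
  lnr_lm <- (d_ref + 35) / 485
  fit <- transfer_lambda_cross_regime(d_ref, lnr_lm, 35)
  expect_equal(unname(coef(fit)["scale_nm"]), 485, tolerance = 1e-9)
  # 2% multiplicative noise on the log-attenuations, seeded
  lnr_noisy <- with_seed_test(7, lnr_lm * (1 + rnorm(10, sd = 0.02)))
  fitn <- transfer_lambda_cross_regime(d_ref, lnr_noisy, 35)
  oracle <- sum(lnr_noisy * (d_ref + 35)) / sum(lnr_noisy^2)
  expect_equal(unname(coef(fitn)["scale_nm"]), oracle, tolerance = 1e-12)
  expect_lt(abs(coef(fitn)["scale_nm"] - 485) / 485, 0.03)
  expect_error(transfer_lambda_cross_regime(30, 0.1, 35),
               class = "pairing_error")
  # id mismatch
  expect_error(
    transfer_lambda_cross_regime(c(a = 30, b = 40), c(a = 0.1, c = 0.2), 35),
    class = "pairing_error"
  )
})

test_that("fit_lambda_als equals the through-origin regression oracle", {
  lnr <- seq(0.01, 0.15, length.out = 5)
  fit <- fit_lambda_als(600 * lnr, lnr)
  expect_equal(unname(coef(fit)["scale_nm"]), 600, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["correction_nm"]), 0)
  d_noisy <- with_seed_test(9, 1750 * lnr + rnorm(5, sd = 3))
  fitn <- fit_lambda_als(d_noisy, lnr)
  expect_equal(unname(coef(fitn)["scale_nm"]),
               sum(d_noisy * lnr) / sum(lnr^2), tolerance = 1e-12)
  expect_error(fit_lambda_als(c(1, 2), c(0, 0)),
               class = "insufficient_data")
})

test_that("lambda_fit behaves like a classed model object", {
  s <- simulate_calibration_set(305, 4, n_holes = 10, noise_sd_nm = 2,
                                seed = 5)
  fit <- fit_lambda_filter(s, correction_nm = 4)
  expect_s3_class(fit, "lambda_fit")
  expect_named(coef(fit), c("scale_nm", "correction_nm"))
  expect_length(residuals(fit), 10)
  expect_equal(predict(fit, 0.2),
               unname(coef(fit)["scale_nm"] * 0.2 - 4))
  expect_output(print(fit), "scale_nm")
  expect_output(print(summary(fit)), "residual sigma")
  prof <- as_profile(fit, 200, "M_SA")
  expect_s3_class(prof, "calibration_profile")
  expect_equal(prof$scale_nm, unname(coef(fit)["scale_nm"]))
})

test_that("counts_from_flux converts electron flux linearly", {
  k2 <- camera_profile("K2")
  expect_equal(counts_from_flux(12.9, k2), 10.7)
  expect_equal(counts_from_flux(0, k2), 0)
  expect_equal(counts_from_flux(25.8, k2), 21.4)
  expect_error(counts_from_flux(-1, k2), class = "domain_error")
})

test_that("count-rate guard warns above the ceiling but never blocks", {
  k2 <- camera_profile("K2")
  expect_equal(check_count_rate(9, k2)$verdict, "pass")
  expect_equal(check_count_rate(10, k2)$verdict, "pass")  # inclusive boundary
  expect_warning(v <- check_count_rate(12, k2), class = "count_rate_guard")
  expect_equal(v$verdict, "warn")
})

test_that("calibration CSV and profile registry round-trip", {
  s <- simulate_calibration_set(305, 4, n_holes = 8, noise_sd_nm = 1,
                                seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(s, path)
  s2 <- read_calibration_csv(path)
  expect_equal(s2$log_attenuation, s$log_attenuation)
  expect_equal(s2$true_thickness_nm, s$true_thickness_nm)
  expect_equal(s2$is_vacuum, s$is_vacuum)
  # missing column is reported by name
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(hole_id = 1, log_attenuation = 0.1), bad,
            row.names = FALSE)
  expect_error(read_calibration_csv(bad), "true_thickness_nm",
               class = "parse_error")

  reg <- withr::local_tempfile(fileext = ".cfg")
  profs <- list(default_profile(200, "M_SA", "FILTER"),
                default_profile(300, "LM", "ALS"))
  write_profile_registry(profs, reg)
  back <- read_profile_registry(reg)
  expect_length(back, 2)
  expect_equal(back[["200/M_SA/FILTER"]]$scale_nm, 305)
  expect_equal(back[["300/LM/ALS"]]$scale_nm, 1750)
  expect_equal(back[["300/LM/ALS"]]$correction_nm, 0)
})
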