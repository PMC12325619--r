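# ACM / ISM / ratio-spectrum methods and the joint resolver.

test_that("the correction factor is the stated absorbance ratio", {
  wl <- 200:400
  s <- uv_spectrum(wl, ifelse(wl < 300, 0.40, 0.80))
  expect_equal(compute_fac(s, acm_config()), 0.5)

  # concentration independence under Beer-Lambert
  t6 <- simulate_measurement(list(list(model = preset_trim(), conc = 6)),
                             noise_sd = 0)
  t12 <- simulate_measurement(list(list(model = preset_trim(), conc = 12)),
                              noise_sd = 0)
  expect_equal(compute_fac(t6, acm_config()), compute_fac(t12, acm_config()),
               tolerance = 1e-12)

  # degenerate divisor
  z <- uv_spectrum(wl, ifelse(wl < 300, 0.40, 0))
  expect_error(compute_fac(z, acm_config()), "degenerate divisor")
})

test_that("absorption correction recovers a constructed mixture exactly", {
  # closed-form oracle: unit absorptivities a_H(271) = 0.069,
  # a_T(361) = 0.0803, a_T(271) = 0.5 * a_T(361), narrow non-overlapping
  # bands, concentrations (4, 6); corrected absorbance must equal
  # 4 * 0.069 and the estimates must be exact
  h <- analyte_model("HCTZ", list(band(271, 10, 0.069)))
  t <- analyte_model("TRIM", list(band(361, 10, 0.0803),
                                  band(271, 10, 0.5 * 0.0803)))
  g <- default_grid()
  concs <- seq(2, 14, length.out = 5)
  sig_at <- function(model, lambda) vapply(concs, function(cc)
    amplitude_at(simulate_measurement(list(list(model = model, conc = cc)),
                                      noise_sd = 0, grid = g), lambda),
    numeric(1))
  cal_h <- fit_calibration(concs, sig_at(h, 271), "HCTZ", 271)
  cal_t <- fit_calibration(concs, sig_at(t, 361), "TRIM", 361)
  cfg <- acm_config()
  cfg$f_ac <- compute_fac(
    simulate_measurement(list(list(model = t, conc = 10)), noise_sd = 0,
                         grid = g), cfg)
  expect_equal(cfg$f_ac, 0.5, tolerance = 1e-12)

  mix <- simulate_measurement(list(list(model = h, conc = 4),
                                   list(model = t, conc = 6)),
                              noise_sd = 0, grid = g)
  res <- acm_resolve(mix, cfg, cal_t, cal_h)
  expect_equal(res$intermediates$corrected_absorbance, 4 * 0.069,
               tolerance = 1e-10)
  expect_equal(unname(res$estimates[c("HCTZ", "TRIM")]), c(4, 6),
               tolerance = 1e-9)
  expect_length(res$flags, 0)

  # zero interferent: correction changes nothing
  mix_h <- simulate_measurement(list(list(model = h, conc = 4)),
                                noise_sd = 0, grid = g)
  res_h <- acm_resolve(mix_h, cfg, cal_t, cal_h)
  expect_equal(res_h$intermediates$corrected_absorbance,
               res_h$intermediates$a_interfering, tolerance = 1e-12)
  expect_equal(unname(res_h$estimates["HCTZ"]), 4, tolerance = 1e-9)

  # all-zero mixture with (numerically) zero-intercept calibrations
  blank <- simulate_measurement(list(list(model = h, conc = 0)),
                                noise_sd = 0, grid = g)
  res_0 <- acm_resolve(blank, cfg, cal_t, cal_h)
  expect_equal(unname(res_0$estimates), c(0, 0), tolerance = 1e-9)
})

test_that("isoabsorptive point search handles symmetry and degeneracy", {
  a <- absorptivity_spectrum(one_band_model(260, 20, 0.1))
  b <- absorptivity_spectrum(one_band_model(280, 20, 0.1))
  iso <- find_isoabsorptive_point(a, b, c(262, 278))
  expect_equal(iso$lambda, 270, tolerance = 1e-9)   # by symmetry

  expect_error(find_isoabsorptive_point(a, a, c(262, 278)), "degenerate")
  expect_error(find_isoabsorptive_point(a, b, c(290, 300)),
               "no isoabsorptive point")
})

test_that("isoabsorptive resolution conserves and splits the total", {
  suite <- noiseless_suite()
  e <- suite$ism
  mix <- noiseless_spectrum(4, 6)
  res <- ism_resolve(mix, e$lambda_iso, e$calib_iso, e$calib_free)
  expect_equal(res$intermediates$c_total, 10, tolerance = 0.01 * 10)
  expect_equal(unname(res$estimates[c("HCTZ", "TRIM")]), c(4, 6),
               tolerance = 0.01 * 6)
  # conservation is structural
  expect_equal(sum(res$estimates), res$intermediates$c_total,
               tolerance = 1e-12)

  # single-analyte edge cases
  only_h <- noiseless_spectrum(5, 0)
  res_h <- ism_resolve(only_h, e$lambda_iso, e$calib_iso, e$calib_free)
  expect_equal(unname(res_h$estimates["HCTZ"]), res_h$intermediates$c_total,
               tolerance = 1e-9)

  only_t <- noiseless_spectrum(0, 8)
  res_t <- ism_resolve(only_t, e$lambda_iso, e$calib_iso, e$calib_free)
  expect_lt(abs(res_t$estimates[["HCTZ"]]), 0.05)
  if (res_t$estimates[["HCTZ"]] < 0)
    expect_true("negative-estimate" %in% res_t$flags)
})

test_that("ratio spectra cancel the divisor analyte into a constant", {
  g <- default_grid()
  ut <- absorptivity_spectrum(preset_trim(), grid = g)

  # spectrum divided by itself: constant 1 on unmasked channels
  r_self <- ratio_spectrum(ut, ut, 1, floor = 1e-12)
  ok <- !is.na(r_self$absorbances)
  expect_equal(r_self$absorbances[ok], rep(1, sum(ok)), tolerance = 1e-12)

  # pure divisor analyte at 8 ug/mL over its own unit spectrum x 10
  t8 <- simulate_measurement(list(list(model = preset_trim(), conc = 8)),
                             noise_sd = 0, grid = g)
  r <- ratio_spectrum(t8, ut, 10)
  ok <- !is.na(r$absorbances)
  expect_equal(r$absorbances[ok], rep(0.8, sum(ok)), tolerance = 1e-10)
  expect_equal(r$meta$n_masked, sum(!ok))
  expect_gt(r$meta$n_masked, 0)   # the divisor does vanish off-band

  # constant ratio: delta-P = 0 and derivative = 0 (interferent eliminated)
  expect_equal(rdf_delta(r, 273, 293), 0, tolerance = 1e-10)
  d <- ratio_derivative(r, 51, 2)
  ok <- !is.na(d$absorbances)
  expect_equal(max(abs(d$absorbances[ok])), 0, tolerance = 1e-9)

  # masked wavelength refuses a read-off
  expect_error(rdf_delta(r, 210, 293), "masked")
})

test_that("ratio derivative reproduces the slope of a ramp", {
  wl <- seq(240, 320, 0.1)
  ramp <- uv_spectrum(wl, 0.05 * wl)
  d <- ratio_derivative(ramp, 9, 2)
  inner <- seq(20, length(wl) - 20)
  expect_equal(d$absorbances[inner], rep(0.05, length(inner)),
               tolerance = 1e-10)
  expect_error(ratio_derivative(ramp, 10, 2), "odd")
  expect_error(ratio_derivative(ramp, 3, 4), "odd|polyorder")
})

test_that("ratio read-offs are linear in analyte, invariant to interferent", {
  suite <- noiseless_suite()
  br_h <- suite$rdf[[1]]   # HCTZ branch: TRIM 10 ug/mL divisor
  cfg <- br_h$config

  concs <- seq(2, 12, 2)
  dp <- vapply(concs, function(cc) {
    r <- ratio_spectrum(noiseless_spectrum(cc, 6), br_h$divisor_unit,
                        cfg$divisor_concentration)
    rdf_delta(r, cfg$rdf_pair[1], cfg$rdf_pair[2])
  }, numeric(1))
  expect_equal(abs(cor(concs, dp)), 1, tolerance = 1e-12)

  # fixed analyte, interferent swept: delta-P constant to < 0.1%
  dp_i <- vapply(concs, function(ct) {
    r <- ratio_spectrum(noiseless_spectrum(6, ct), br_h$divisor_unit,
                        cfg$divisor_concentration)
    rdf_delta(r, cfg$rdf_pair[1], cfg$rdf_pair[2])
  }, numeric(1))
  expect_lt(diff(range(dp_i)) / abs(mean(dp_i)), 0.001)
})

test_that("the joint resolver runs all five methods and isolates failures", {
  suite <- noiseless_suite()
  mix <- noiseless_spectrum(4, 6)
  res <- resolve_all(mix, suite)
  expect_named(res, c("acm", "ism", "fsd", "rdf", "rdm"))
  for (r in res) {
    expect_s3_class(r, "resolved_concentrations")
    expect_equal(unname(r$estimates[c("HCTZ", "TRIM")]), c(4, 6),
                 tolerance = 0.01)   # within 1% of truth
  }

  # blank input with (numerically) zero-intercept calibrations
  blank <- noiseless_spectrum(0, 0)
  res_b <- resolve_all(blank, suite)
  for (r in res_b[c("acm", "ism", "rdf", "rdm")])
    expect_equal(unname(r$estimates), c(0, 0), tolerance = 1e-6)

  # a missing calibration yields a structured failure, others still resolve
  broken <- suite
  broken$fsd <- NULL
  res_p <- resolve_all(mix, broken)
  expect_s3_class(res_p$fsd, "method_failure")
  expect_match(res_p$fsd$error, "not calibrated")
  expect_s3_class(res_p$acm, "resolved_concentrations")
  expect_s3_class(res_p$rdm, "resolved_concentrations")
})
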