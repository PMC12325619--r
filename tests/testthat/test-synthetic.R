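test_that("presets carry the anchoring band structure", {
  h <- preset_hctz()
  centers <- vapply(h$bands, `[[`, numeric(1), "center")
  expect_true(271 %in% centers)
  expect_true(221 %in% centers)

  # TRIM's global maximum sits at 361 nm
  ut <- absorptivity_spectrum(preset_trim())
  expect_lt(abs(peak_wavelength(ut) - 361), 0.5)

  # 361 nm is a genuine zero-contribution point for HCTZ
  uh <- absorptivity_spectrum(preset_hctz())
  expect_lt(amplitude_at(uh, 361), 0.01 * amplitude_at(uh, 271))
})

test_that("preset unit spectra cross once in the isoabsorptive window", {
  # oracle: exhaustive sign-change scan on a 0.001 nm grid
  fine <- wavelength_grid(260, 272, 0.001)
  # bands centered outside this deliberately narrow scan window are fine;
  # only their in-window tails matter for the crossing
  uh <- suppressWarnings(absorptivity_spectrum(preset_hctz(), grid = fine))
  ut <- suppressWarnings(absorptivity_spectrum(preset_trim(), grid = fine))
  d <- uh$absorbances - ut$absorbances
  flips <- which(d[-length(d)] * d[-1] < 0)
  expect_length(flips, 1)
  lambda_oracle <- grid_wavelengths(fine)[flips]
  expect_gte(lambda_oracle, 265)
  expect_lte(lambda_oracle, 268.5)

  # package search on the working grid agrees with the brute-force scan
  iso <- find_isoabsorptive_point(absorptivity_spectrum(preset_hctz()),
                                  absorptivity_spectrum(preset_trim()),
                                  window = c(262, 271))
  expect_lt(abs(iso$lambda - lambda_oracle), 0.01)
})

test_that("band shapes honour their FWHM parameterization", {
  g <- default_grid()
  s1 <- absorptivity_spectrum(one_band_model(300, 20, 0.4), grid = g)
  expect_equal(amplitude_at(s1, 300), 0.4)          # peak = peak_absorptivity
  expect_equal(measure_fwhm(s1), 20, tolerance = 1e-3)

  # solvent broadening doubles the measured FWHM at factor 2
  s2 <- absorptivity_spectrum(one_band_model(300, 20, 0.4),
                              solvent_model("x", broadening_factor = 2),
                              grid = g)
  expect_equal(measure_fwhm(s2), 40, tolerance = 1e-3)

  # empty model gives an all-zero (blank) spectrum
  blank <- absorptivity_spectrum(analyte_model("none"), grid = g)
  expect_true(all(blank$absorbances == 0))

  # band shifted outside the grid is recorded in metadata
  expect_warning(
    out <- absorptivity_spectrum(one_band_model(445, 20, 0.4),
                                 solvent_model("x", shift = 20), grid = g),
    "outside grid")
  expect_true(length(out$meta$warnings) == 1)
})

test_that("broadening never sharpens or raises a band", {
  fwhms <- peaks <- numeric(0)
  for (bf in c(1, 1.5, 2, 3)) {
    s <- absorptivity_spectrum(one_band_model(320, 18, 0.3),
                               solvent_model("x", broadening_factor = bf))
    fwhms <- c(fwhms, measure_fwhm(s))
    peaks <- c(peaks, max(s$absorbances))
  }
  expect_true(all(diff(fwhms) > 0))
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("mixtures obey Beer-Lambert additivity and linearity", {
  g <- default_grid()
  mix <- noiseless_spectrum(4, 6)
  a <- simulate_measurement(list(list(model = preset_hctz(), conc = 4)),
                            noise_sd = 0, grid = g)
  b <- simulate_measurement(list(list(model = preset_trim(), conc = 6)),
                            noise_sd = 0, grid = g)
  expect_equal(mix$absorbances, a$absorbances + b$absorbances,
               tolerance = 1e-14)

  # noiseless absorbance at any wavelength is exactly linear in concentration
  concs <- 1:6
  amps <- vapply(concs, function(cc)
    amplitude_at(noiseless_spectrum(cc, 0), 271), numeric(1))
  expect_equal(cor(concs, amps), 1, tolerance = 1e-12)

  # all-zero blank
  blank <- noiseless_spectrum(0, 0)
  expect_true(all(blank$absorbances == 0))

  expect_error(noiseless_spectrum(-1, 2), "negative concentration")
})

test_that("seeded simulation is bit-reproducible", {
  comp <- list(list(model = preset_hctz(), conc = 5))
  s1 <- simulate_measurement(comp, noise_sd = 0.002, seed = 11)
  s2 <- simulate_measurement(comp, noise_sd = 0.002, seed = 11)
  s3 <- simulate_measurement(comp, noise_sd = 0.002, seed = 12)
  expect_identical(s1$absorbances, s2$absorbances)
  expect_false(identical(s1$absorbances, s3$absorbances))
})

test_that("solvent ranking applies the exclusion and ordering rules", {
  d <- descriptor_table(c("A", "B", "C"),
                        solvation = c(1, 2, -2),
                        interaction = c(5, 3, 1),
                        dielectric = c(25, 33, 80))
  out <- rank_solvents(d, "X")
  expect_equal(out$solvent[out$verdict == "excluded"], "C")
  ranked <- out[out$verdict == "ranked", ]
  expect_equal(ranked$solvent, c("B", "A"))
  expect_equal(ranked$rank, c(1L, 2L))

  # all exothermic: everything excluded, empty ranking with verdicts
  d2 <- descriptor_table(c("A", "B"), c(-1, -3), c(2, 4), c(25, 33))
  out2 <- rank_solvents(d2, "X")
  expect_true(all(out2$verdict == "excluded"))
  expect_true(all(is.na(out2$rank)))

  # equal interaction magnitude: lower dielectric first
  d3 <- descriptor_table(c("A", "B"), c(1, 1), c(3, 3), c(60, 20))
  out3 <- rank_solvents(d3, "X")
  expect_equal(out3$solvent[out3$rank == 1], "B")

  # missing field named in the error
  d4 <- d
  d4$interaction_energy[2] <- NA
  expect_error(rank_solvents(d4, "X"), "solvent B.*interaction_energy")
})
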