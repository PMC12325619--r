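# Shared fixtures, all built in code.

# single-gaussian analyte for shape-level checks
one_band_model <- function(center = 300, fwhm = 20, peak = 0.5,
                           shape = "gaussian") {
  analyte_model("toy", list(band(center, fwhm, peak, shape)))
}

noiseless_spectrum <- function(conc_a, conc_b, grid = default_grid()) {
  simulate_measurement(list(list(model = preset_hctz(), conc = conc_a),
                            list(model = preset_trim(), conc = conc_b)),
                       noise_sd = 0, grid = grid)
}

# calibrating the five methods on noiseless standards is deterministic and
# moderately expensive; memoize across test files
.suite_cache <- new.env(parent = emptyenv())
noiseless_suite <- function() {
  if (is.null(.suite_cache$suite))
    .suite_cache$suite <- calibrate_methods(study_config(noise_sd = 0))
  .suite_cache$suite
}

# toy solvent-descriptor table builder
descriptor_table <- function(solvent, solvation, interaction, dielectric) {
  do.call(rbind, lapply(seq_along(solvent), function(i)
    data.frame(solvent = solvent[i], analyte = "X",
               solvation_energy = solvation[i], hb_capacity = 2,
               interaction_energy = interaction[i], dipole = 1.5,
               dielectric = dielectric[i])))
}
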