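# Parametric synthetic-spectra generator.
#
# Unit-concentration absorptivity spectra are sums of analytic band shapes;
# mixtures follow Beer-Lambert additivity with optional homoscedastic
# Gaussian noise. The presets emulate the hydrochlorothiazide (HCTZ) /
# triamterene (TRIM) system in ethanol: band *positions* (271/221 nm for
# HCTZ, 361 nm for TRIM), the isoabsorptive crossing near 266.8 nm and the
# zero-contribution point at 361 nm are literature anchors; widths and
# relative amplitudes are tuned constants (no molar absorptivities are
# published).

#' Absorption band
#'
#' @param center Band center in nm.
#' @param fwhm Full width at half maximum in nm, > 0.
#' @param peak_absorptivity Peak absorptivity in AU mL / ug (absorbance of a
#'   1 ug/mL solution at the band center), >= 0.
#' @param shape `"gaussian"` (default) or `"lorentzian"`.
#' @return A `band` object.
#' @export
band <- function(center, fwhm, peak_absorptivity,
                 shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (!(fwhm > 0)) stop("fwhm must be > 0", call. = FALSE)
  if (peak_absorptivity < 0)
    stop("peak_absorptivity must be >= 0", call. = FALSE)
  structure(list(center = center, fwhm = fwhm,
                 peak_absorptivity = peak_absorptivity, shape = shape),
            class = "band")
}

eval_band <- function(b, lambda, broadening = 1, shift = 0) {
  c0 <- b$center + shift
  w <- b$fwhm * broadening
  p <- b$peak_absorptivity
  switch(b$shape,
    gaussian   = p * exp(-4 * log(2) * (lambda - c0)^2 / w^2),
    lorentzian = p * (w / 2)^2 / ((lambda - c0)^2 + (w / 2)^2))
}

#' Analyte model: a named set of absorption bands
#'
#' An empty band list is allowed and produces an all-zero (blank) spectrum.
#'
#' @param name Analyte label.
#' @param bands List of [band()] objects.
#' @return An `analyte_model` object.
#' @export
analyte_model <- function(name, bands = list()) {
  if (inherits(bands, "band")) bands <- list(bands)
  ok <- vapply(bands, inherits, logical(1), what = "band")
  if (length(bands) && !all(ok))
    stop("bands must be a list of band objects", call. = FALSE)
  structure(list(name = name, bands = bands), class = "analyte_model")
}

#' Preset hydrochlorothiazide (HCTZ) model
#'
#' Two Gaussian bands at 271 nm and 221 nm. The 271 nm peak absorptivity
#' (0.0690 AU mL/ug) mirrors the published zero-order calibration slope at
#' that wavelength; the narrow 16 nm width reflects the solvent's narrowing
#' effect on HCTZ in ethanol and, together with the TRIM preset, places the
#' isoabsorptive crossing at 266.8 nm and makes 361 nm a true
#' zero-contribution point for HCTZ (absorptivity < 1e-30 of the 271 nm
#' value).
#'
#' @return An [analyte_model()].
#' @export
preset_hctz <- function() {
  analyte_model("HCTZ", list(
    band(271, 16, 0.0690),
    band(221, 26, 0.1100)
  ))
}

#' Preset triamterene (TRIM) model
#'
#' Main Gaussian band at 361 nm (peak absorptivity 0.0803 AU mL/ug, mirroring
#' the published 361 nm calibration slope) plus two shorter-wavelength bands
#' (258 nm and a weak 290 nm shoulder). The short-wavelength amplitudes and
#' widths are tuned so that (a) the unit spectra of the two presets cross at
#' 266.8 nm, (b) the global maximum stays at 361 nm, and (c) the
#' ratio-spectrum divisors remain above the masking floor across the
#' 244-293 nm working regions.
#'
#' @return An [analyte_model()].
#' @export
preset_trim <- function() {
  analyte_model("TRIM", list(
    band(361, 42, 0.0803),
    band(258, 26, 0.0770),
    band(290, 24, 0.0140)
  ))
}

#' Solvent model
#'
#' Captures the direction of the solvent effect reported for this system:
#' stronger solute-solvent interaction broadens the solute's bands. The
#' broadening factor multiplies every band FWHM; the shift adds to every
#' band center.
#'
#' @param name Solvent label.
#' @param broadening_factor Dimensionless multiplier on band FWHM, > 0.
#' @param shift Additive band-center shift in nm.
#' @return A `solvent_model` object.
#' @export
solvent_model <- function(name = "ethanol", broadening_factor = 1, shift = 0) {
  if (!(broadening_factor > 0))
    stop("broadening_factor must be > 0", call. = FALSE)
  structure(list(name = name, broadening_factor = broadening_factor,
                 shift = shift),
            class = "solvent_model")
}

#' Illustrative interaction-energy to broadening mapping
#'
#' The study direction is qualitative only (stronger interaction, broader
#' bands); this linear mapping `1 + k * |interaction_energy|` is provided for
#' demonstrations and makes no claim to the (unpublished) functional form.
#'
#' @param interaction_energy Solute-solvent interaction energy, kcal/mol
#'   (magnitude used).
#' @param k Slope per kcal/mol (default 0.02).
#' @return Broadening factor >= 1.
#' @export
broadening_from_interaction <- function(interaction_energy, k = 0.02) {
  1 + k * abs(interaction_energy)
}

#' Unit-concentration absorptivity spectrum of an analyte
#'
#' Sums the model's bands, with the solvent's broadening applied to every
#' FWHM and its shift applied to every center. Bands pushed outside the grid
#' are still evaluated (their in-grid tail) but a warning is recorded in the
#' spectrum metadata.
#'
#' @param model An [analyte_model()].
#' @param solvent A [solvent_model()].
#' @param grid A [wavelength_grid()].
#' @return A [uv_spectrum()] of the 1 ug/mL absorbance.
#' @export
absorptivity_spectrum <- function(model, solvent = solvent_model(),
                                  grid = default_grid()) {
  lambda <- grid_wavelengths(grid)
  a <- numeric(length(lambda))
  warn <- character(0)
  for (b in model$bands) {
    c0 <- b$center + solvent$shift
    if (c0 < grid$start || c0 > grid$stop)
      warn <- c(warn, sprintf("band at %g nm shifted outside grid", c0))
    a <- a + eval_band(b, lambda, solvent$broadening_factor, solvent$shift)
  }
  meta <- list(analyte = model$name, concentration = 1,
               solvent = solvent$name)
  if (length(warn)) {
    meta$warnings <- warn
    warning(paste(warn, collapse = "; "), call. = FALSE)
  }
  uv_spectrum(lambda, a, meta)
}

#' Simulate a measured spectrum of a mixture
#'
#' Beer-Lambert forward model: `A(lambda) = sum_i c_i * a_i(lambda) +
#' eps(lambda)` with `eps` i.i.d. Gaussian of standard deviation `noise_sd`
#' (additive, homoscedastic, in AU). The default `noise_sd` of 0.002 AU was
#' chosen so synthetic replicate %RSDs land in the 0.1-2.5% range typical of
#' routine UV assays.
#'
#' @param components List of components, each a `list(model = , conc = )`
#'   with an [analyte_model()] and a concentration in ug/mL (>= 0).
#' @param solvent A [solvent_model()].
#' @param noise_sd Noise standard deviation in AU, >= 0.
#' @param seed Optional integer; when given, the draw is reproducible and
#'   independent of the surrounding RNG stream state at a fixed seed. When
#'   `NULL`, noise is drawn from the current RNG stream.
#' @param grid A [wavelength_grid()].
#' @return A [uv_spectrum()] with component metadata.
#' @export
simulate_measurement <- function(components, solvent = solvent_model(),
                                 noise_sd = 0.002, seed = NULL,
                                 grid = default_grid()) {
  if (inherits(components, "analyte_model"))
    stop("components must be a list of list(model=, conc=)", call. = FALSE)
  if (!(noise_sd >= 0)) stop("noise_sd must be >= 0", call. = FALSE)
  lambda <- grid_wavelengths(grid)
  a <- numeric(length(lambda))
  labels <- character(0)
  concs <- numeric(0)
  for (comp in components) {
    if (is.null(comp$model) || is.null(comp$conc))
      stop("each component needs fields model and conc", call. = FALSE)
    if (comp$conc < 0)
      stop("negative concentration for ", comp$model$name, call. = FALSE)
    for (b in comp$model$bands)
      a <- a + comp$conc *
        eval_band(b, lambda, solvent$broadening_factor, solvent$shift)
    labels <- c(labels, comp$model$name)
    concs <- c(concs, comp$conc)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    a <- a + rnorm(length(a), 0, noise_sd)
  }
  uv_spectrum(lambda, a,
              list(analytes = paste(labels, collapse = "+"),
                   concentrations = paste(concs, collapse = "+"),
                   solvent = solvent$name, noise_sd = noise_sd,
                   seed = if (is.null(seed)) NA else seed))
}

# ---- solvent-descriptor ranking (greenness-by-design decision rule) ----

SOLVENT_COLS <- c("solvent", "analyte", "solvation_energy", "hb_capacity",
                  "interaction_energy", "dipole", "dielectric")

#' Read a solvent-descriptor table
#'
#' Long-format CSV with columns `solvent, analyte, solvation_energy,
#' hb_capacity, interaction_energy, dipole, dielectric`. Energies in
#' kcal/mol (negative solvation energy = exothermic), dipole in Debye,
#' dielectric dimensionless.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_solvent_descriptors <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SOLVENT_COLS, names(d))
  if (length(missing_cols))
    stop("descriptor table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d
}

#' Rank candidate solvents for an analyte of interest
#'
#' Implements the in-silico solvent-selection decision rule: solvents showing
#' exothermic solvation (negative solvation energy) for *any* analyte are
#' excluded outright; the remaining solvents are ranked by ascending
#' magnitude of their interaction energy with the analyte of interest
#' (weakest interaction first, i.e. least band broadening). Ties break by
#' lower dielectric constant, then input order.
#'
#' @param descriptors Data frame as from [read_solvent_descriptors()].
#' @param analyte_of_interest Analyte label to rank for.
#' @return Data frame with columns `solvent`, `verdict` (`"ranked"` or
#'   `"excluded"`), `rank` (NA for excluded), `interaction_energy`,
#'   `rationale`; ranked solvents first, in rank order.
#' @export
rank_solvents <- function(descriptors, analyte_of_interest) {
  missing_cols <- setdiff(SOLVENT_COLS, names(descriptors))
  if (length(missing_cols))
    stop("descriptor table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  solvents <- unique(descriptors$solvent)
  analytes <- unique(descriptors$analyte)
  for (sv in solvents) {
    sub <- descriptors[descriptors$solvent == sv, ]
    for (an in analytes)
      if (!an %in% sub$analyte)
        stop("solvent ", sv, " lacks a row for analyte ", an, call. = FALSE)
    for (col in setdiff(SOLVENT_COLS, c("solvent", "analyte")))
      if (anyNA(sub[[col]]))
        stop("solvent ", sv, ": missing value in field ", col, call. = FALSE)
  }
  if (!analyte_of_interest %in% analytes)
    stop("no descriptor rows for analyte ", analyte_of_interest,
         call. = FALSE)

  rows <- lapply(seq_along(solvents), function(k) {
    sv <- solvents[k]
    sub <- descriptors[descriptors$solvent == sv, ]
    exo <- sub$analyte[sub$solvation_energy < 0]
    tgt <- sub[sub$analyte == analyte_of_interest, ][1, ]
    if (length(exo)) {
      data.frame(solvent = sv, verdict = "excluded", rank = NA_integer_,
                 interaction_energy = abs(tgt$interaction_energy),
                 dielectric = tgt$dielectric, order_in = k,
                 rationale = paste0("exothermic solvation for ",
                                    paste(exo, collapse = ", ")))
    } else {
      data.frame(solvent = sv, verdict = "ranked", rank = NA_integer_,
                 interaction_energy = abs(tgt$interaction_energy),
                 dielectric = tgt$dielectric, order_in = k,
                 rationale = sprintf(
                   "interaction energy magnitude %.4g kcal/mol with %s",
                   abs(tgt$interaction_energy), analyte_of_interest))
    }
  })
  out <- do.call(rbind, rows)
  ranked <- out[out$verdict == "ranked", ]
  excl <- out[out$verdict == "excluded", ]
  if (nrow(ranked)) {
    o <- order(ranked$interaction_energy, ranked$dielectric, ranked$order_in)
    ranked <- ranked[o, ]
    ranked$rank <- seq_len(nrow(ranked))
  }
  res <- rbind(ranked, excl)
  rownames(res) <- NULL
  res$order_in <- NULL
  res
}
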