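# The five spectral-resolution methods for a two-component mixture:
#   ACM  absorption correction at 271/361 nm via the correction factor F_ac
#   ISM  isoabsorptive-point quantitation (total at the crossing, the
#        interference-free analyte at its zero-contribution point)
#   FSD  Fourier self-deconvolution amplitude read-off (see fsd.R)
#   RDF  ratio-difference spectrophotometry (delta-P between two wavelengths
#        of the ratio spectrum)
#   RDM  first derivative of the ratio spectrum

#' Resolved concentrations from one method
#'
#' Container for per-analyte estimates plus the intermediate signals the
#' method used. A `"negative-estimate"` flag is set whenever any estimate is
#' below zero; estimates are reported as computed, never truncated.
#'
#' @param method Method label (e.g. `"ACM"`).
#' @param estimates Named numeric vector of concentrations (ug/mL).
#' @param intermediates Named list of intermediate signals.
#' @param flags Character vector of condition flags.
#' @return A `resolved_concentrations` object.
#' @export
resolved_concentrations <- function(method, estimates,
                                    intermediates = list(),
                                    flags = character(0)) {
  if (any(estimates < 0, na.rm = TRUE))
    flags <- union(flags, "negative-estimate")
  structure(list(method = method, estimates = estimates,
                 intermediates = intermediates, flags = flags),
            class = "resolved_concentrations")
}

#' @export
print.resolved_concentrations <- function(x, ...) {
  cat(sprintf("<%s> ", x$method))
  cat(paste(sprintf("%s = %.4g ug/mL", names(x$estimates), x$estimates),
            collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# ---- ACM ---------------------------------------------------------------

#' Absorption-correction configuration
#'
#' @param lambda_interfering Wavelength (nm) where the analyte of interest is
#'   measured but the second component still absorbs (default 271).
#' @param lambda_free Wavelength (nm) where only the second component
#'   absorbs (default 361).
#' @param f_ac Correction factor (ratio of the interferent's absorbances at
#'   the two wavelengths); usually filled in by [compute_fac()].
#' @param divisor_floor Minimum absorbance (AU) accepted at `lambda_free`
#'   when deriving `f_ac` (default 0.01).
#' @return An `acm_config` object.
#' @export
acm_config <- function(lambda_interfering = 271, lambda_free = 361,
                       f_ac = NULL, divisor_floor = 0.01) {
  if (lambda_interfering == lambda_free)
    stop("lambda_interfering must differ from lambda_free", call. = FALSE)
  if (!is.null(f_ac) && !(f_ac > 0))
    stop("f_ac must be > 0 when set", call. = FALSE)
  if (!(divisor_floor > 0)) stop("divisor_floor must be > 0", call. = FALSE)
  structure(list(lambda_interfering = lambda_interfering,
                 lambda_free = lambda_free, f_ac = f_ac,
                 divisor_floor = divisor_floor),
            class = "acm_config")
}

#' Correction factor from a pure interferent spectrum
#'
#' `F_ac = A(lambda_interfering) / A(lambda_free)` of a single-component
#' spectrum of the interferent. Under Beer-Lambert the ratio is independent
#' of the standard's concentration.
#'
#' @param pure_interferent A [uv_spectrum()] of the pure interferent.
#' @param cfg An [acm_config()].
#' @return The correction factor (dimensionless).
#' @export
compute_fac <- function(pure_interferent, cfg = acm_config()) {
  a_free <- amplitude_at(pure_interferent, cfg$lambda_free)
  if (is.na(a_free) || a_free <= cfg$divisor_floor)
    stop(sprintf(
      "degenerate divisor: A(%g nm) = %.4g is at or below the floor %g",
      cfg$lambda_free, a_free, cfg$divisor_floor), call. = FALSE)
  amplitude_at(pure_interferent, cfg$lambda_interfering) / a_free
}

#' Resolve a mixture by absorption correction
#'
#' The interferent is read directly at its interference-free wavelength; its
#' contribution at the analyte's wavelength is then removed as
#' `A(lambda_interfering) - F_ac * A(lambda_free)` before inverting the
#' analyte's calibration.
#'
#' @param mixture Mixture [uv_spectrum()] covering both wavelengths.
#' @param cfg An [acm_config()] with `f_ac` set.
#' @param calib_interferent_free Calibration of the interferent at
#'   `lambda_free`.
#' @param calib_analyte_interfering Calibration of the analyte at
#'   `lambda_interfering` (fitted on pure standards).
#' @param noise_tol Measurement noise scale in AU; a corrected absorbance
#'   below `-3 * noise_tol` is flagged (default 0.002).
#' @return A [resolved_concentrations()].
#' @export
acm_resolve <- function(mixture, cfg, calib_interferent_free,
                        calib_analyte_interfering, noise_tol = 0.002) {
  if (is.null(cfg$f_ac))
    stop("cfg$f_ac is not set; derive it with compute_fac()", call. = FALSE)
  a_int <- amplitude_at(mixture, cfg$lambda_interfering)
  a_free <- amplitude_at(mixture, cfg$lambda_free)
  corrected <- a_int - cfg$f_ac * a_free
  flags <- character(0)
  if (corrected < -3 * noise_tol)
    flags <- "corrected absorbance below -3 * noise tolerance"
  c_interferent <- predict_conc(calib_interferent_free, a_free)
  c_analyte <- predict_conc(calib_analyte_interfering, corrected)
  est <- c(c_analyte, c_interferent)
  names(est) <- c(calib_analyte_interfering$analyte,
                  calib_interferent_free$analyte)
  resolved_concentrations("ACM", est,
    intermediates = list(a_interfering = a_int, a_free = a_free,
                         f_ac = cfg$f_ac, corrected_absorbance = corrected),
    flags = flags)
}

# ---- ISM ---------------------------------------------------------------

#' Locate the isoabsorptive point of two unit spectra
#'
#' Scans the difference of the two unit-concentration (absorptivity) spectra
#' for sign changes inside `window` and refines each crossing by linear
#' interpolation between the bracketing grid points. When several crossings
#' exist, the one with the largest local slope difference is returned; all
#' are reported.
#'
#' @param unit_a,unit_b Unit-concentration [uv_spectrum()]s on the same grid.
#' @param window Numeric `c(lo, hi)` in nm, within the common span.
#' @return List: `lambda` (the selected crossing, nm) and `crossings`
#'   (data frame of all crossings with their slope differences).
#' @export
find_isoabsorptive_point <- function(unit_a, unit_b, window) {
  if (length(unit_a$wavelengths) != length(unit_b$wavelengths) ||
      any(abs(unit_a$wavelengths - unit_b$wavelengths) > 1e-9))
    stop("unit spectra must share one grid", call. = FALSE)
  wl <- unit_a$wavelengths
  if (window[1] < wl[1] || window[2] > wl[length(wl)])
    stop("window outside the spectra span", call. = FALSE)
  sel <- which(wl >= window[1] & wl <= window[2])
  if (length(sel) < 2) stop("window too narrow", call. = FALSE)
  d <- unit_a$absorbances[sel] - unit_b$absorbances[sel]
  if (max(abs(d)) < 1e-9)
    stop("degenerate: spectra identical within tolerance over the window",
         call. = FALSE)
  step <- wl[2] - wl[1]
  cross_i <- which(d[-length(d)] * d[-1] < 0 | d[-length(d)] == 0)
  cross_i <- cross_i[!(d[cross_i] == 0 & d[cross_i + 1] == 0)]
  if (!length(cross_i))
    stop("no isoabsorptive point found in the window", call. = FALSE)
  lam <- slope_diff <- numeric(length(cross_i))
  for (k in seq_along(cross_i)) {
    i <- cross_i[k]
    lam[k] <- if (d[i] == 0) wl[sel[i]]
              else wl[sel[i]] + step * d[i] / (d[i] - d[i + 1])
    slope_diff[k] <- abs((d[i + 1] - d[i]) / step)
  }
  crossings <- data.frame(lambda = lam, slope_diff = slope_diff)
  list(lambda = lam[which.max(slope_diff)], crossings = crossings)
}

#' Resolve a mixture at the isoabsorptive point
#'
#' At the isoabsorptive wavelength both analytes share one absorptivity, so a
#' single-analyte calibration there reads the *total* concentration of the
#' mixture. The interference-free analyte is read at its own wavelength
#' (taken from its calibration) and the other analyte follows by difference;
#' the conservation `c_other + c_free = c_total` holds by construction.
#'
#' @param mixture Mixture [uv_spectrum()].
#' @param lambda_iso Isoabsorptive wavelength (nm), within the mixture span.
#' @param calib_iso Calibration fitted on one analyte at `lambda_iso`.
#' @param calib_free Calibration of the interference-free analyte at its
#'   zero-contribution wavelength (stored in `calib_free$wavelength`).
#' @return A [resolved_concentrations()] with estimates for both analytes.
#' @export
ism_resolve <- function(mixture, lambda_iso, calib_iso, calib_free) {
  a_iso <- amplitude_at(mixture, lambda_iso)   # range error if outside span
  if (is.na(calib_free$wavelength))
    stop("calib_free must carry its measurement wavelength", call. = FALSE)
  a_free <- amplitude_at(mixture, calib_free$wavelength)
  c_total <- predict_conc(calib_iso, a_iso)
  c_free <- predict_conc(calib_free, a_free)
  c_other <- c_total - c_free
  est <- c(c_other, c_free)
  names(est) <- c(calib_iso$analyte, calib_free$analyte)
  resolved_concentrations("ISM", est,
    intermediates = list(lambda_iso = lambda_iso, a_iso = a_iso,
                         a_free = a_free, c_total = c_total))
}

# ---- ratio-spectrum methods (RDF / RDM) --------------------------------

#' Ratio-method configuration
#'
#' @param divisor_analyte Label of the divisor analyte.
#' @param divisor_concentration Divisor standard concentration in ug/mL, > 0.
#' @param rdf_pair Wavelength pair `c(lambda1, lambda2)` (nm) for the
#'   ratio-difference read-off; the two must differ.
#' @param rdm_wavelength Wavelength (nm) of the ratio-derivative read-off.
#' @param derivative_window Savitzky-Golay window (points, odd, >
#'   `derivative_polyorder`). Default 51 points (5.1 nm on the 0.1 nm grid):
#'   wide enough that differentiation does not dominate the noise budget;
#'   being a linear filter it leaves linearity in concentration and
#'   interferent invariance exact.
#' @param derivative_polyorder Savitzky-Golay polynomial order (default 2).
#' @param divisor_floor Minimum divisor absorbance (AU); channels below it
#'   are masked (default 0.01).
#' @return A `ratio_config` object.
#' @export
ratio_config <- function(divisor_analyte, divisor_concentration,
                         rdf_pair, rdm_wavelength,
                         derivative_window = 51, derivative_polyorder = 2,
                         divisor_floor = 0.01) {
  if (rdf_pair[1] == rdf_pair[2])
    stop("rdf_pair wavelengths must differ", call. = FALSE)
  if (!(divisor_concentration > 0))
    stop("divisor_concentration must be > 0", call. = FALSE)
  if (derivative_window %% 2 != 1 ||
      derivative_window <= derivative_polyorder)
    stop("derivative_window must be odd and > derivative_polyorder",
         call. = FALSE)
  if (!(divisor_floor > 0)) stop("divisor_floor must be > 0", call. = FALSE)
  structure(list(divisor_analyte = divisor_analyte,
                 divisor_concentration = divisor_concentration,
                 rdf_pair = rdf_pair, rdm_wavelength = rdm_wavelength,
                 derivative_window = derivative_window,
                 derivative_polyorder = derivative_polyorder,
                 divisor_floor = divisor_floor),
            class = "ratio_config")
}

#' Default ratio configuration for determining HCTZ
#'
#' Divisor: TRIM standard at 10 ug/mL; ratio-difference pair 273/293 nm;
#' ratio-derivative read-off at 283 nm.
#' @return A [ratio_config()].
#' @export
ratio_config_hctz <- function() {
  ratio_config("TRIM", 10, c(273, 293), 283)
}

#' Default ratio configuration for determining TRIM
#'
#' Divisor: HCTZ standard at 4 ug/mL; ratio-difference pair 244/274 nm;
#' ratio-derivative read-off at 251 nm.
#' @return A [ratio_config()].
#' @export
ratio_config_trim <- function() {
  ratio_config("HCTZ", 4, c(244, 274), 251)
}

#' Ratio spectrum of a mixture over a divisor standard
#'
#' Pointwise quotient of the mixture by `divisor_unit * divisor_conc`. The
#' divisor analyte's contribution becomes the constant
#' `c_divisor / divisor_conc`, so it cancels in amplitude differences and
#' vanishes under differentiation. Channels where the divisor falls below
#' `floor` are masked (`NA`) and counted in the metadata.
#'
#' @param mixture Mixture [uv_spectrum()].
#' @param divisor_unit Unit-concentration [uv_spectrum()] of the divisor
#'   analyte, on the same grid.
#' @param divisor_conc Divisor standard concentration in ug/mL.
#' @param floor Masking floor in AU (default 0.01).
#' @return A [uv_spectrum()] of the (dimensionless) ratio; masked channel
#'   count in `meta$n_masked`.
#' @export
ratio_spectrum <- function(mixture, divisor_unit, divisor_conc,
                           floor = 0.01) {
  if (length(mixture$wavelengths) != length(divisor_unit$wavelengths) ||
      any(abs(mixture$wavelengths - divisor_unit$wavelengths) > 1e-9))
    stop("mixture and divisor must share one grid", call. = FALSE)
  div <- divisor_unit$absorbances * divisor_conc
  mask <- is.na(div) | div < floor
  q <- mixture$absorbances / div
  q[mask] <- NA_real_
  uv_spectrum(mixture$wavelengths, q,
              list(divisor_conc = divisor_conc, floor = floor,
                   n_masked = sum(mask)))
}

#' Ratio-difference amplitude
#'
#' `delta P = P(lambda1) - P(lambda2)` on a ratio spectrum; proportional to
#' the non-divisor analyte's concentration and independent of the divisor
#' analyte's.
#'
#' @param ratio A ratio [uv_spectrum()] from [ratio_spectrum()].
#' @param lambda1,lambda2 Read-off wavelengths in nm.
#' @return The amplitude difference (dimensionless).
#' @export
rdf_delta <- function(ratio, lambda1, lambda2) {
  p <- amplitude_at(ratio, c(lambda1, lambda2))
  if (anyNA(p))
    stop(sprintf("wavelength %g nm is masked in the ratio spectrum",
                 c(lambda1, lambda2)[which(is.na(p))[1]]), call. = FALSE)
  p[1] - p[2]
}

#' First derivative of a ratio spectrum
#'
#' Savitzky-Golay smoothing first derivative with respect to wavelength
#' (units of the ratio per nm). The filter is applied to each contiguous
#' unmasked segment separately, so masked regions stay masked and never leak
#' into neighbouring channels; segments shorter than the window remain
#' masked.
#'
#' @param ratio A ratio [uv_spectrum()].
#' @param window Filter window in points (odd, > `polyorder`, < length).
#' @param polyorder Polynomial order.
#' @return A [uv_spectrum()] of the derivative.
#' @export
ratio_derivative <- function(ratio, window = 51, polyorder = 2) {
  n <- length(ratio$wavelengths)
  if (window %% 2 != 1 || window <= polyorder || window >= n)
    stop("window must be odd, > polyorder and < spectrum length",
         call. = FALSE)
  step <- spectrum_step(ratio)
  y <- ratio$absorbances
  d <- rep(NA_real_, n)
  runs <- rle(!is.na(y))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (runs$values[k] && runs$lengths[k] >= window) {
      idx <- starts[k]:ends[k]
      d[idx] <- sgolayfilt(y[idx], p = polyorder, n = window, m = 1,
                           ts = step)
    }
  }
  meta <- ratio$meta
  meta$units <- "ratio/nm"
  uv_spectrum(ratio$wavelengths, d, meta)
}

# ---- per-method mixture resolvers shared by resolve_all ----------------

#' Resolve a mixture by FSD amplitude read-off
#'
#' Deconvolutes the mixture spectrum and inverts each analyte's calibration
#' at its stored wavelength.
#'
#' @param mixture Mixture [uv_spectrum()].
#' @param cfg An [fsd_config()].
#' @param calib_a,calib_b Calibrations fitted on deconvoluted pure standards;
#'   each must carry its measurement wavelength.
#' @return A [resolved_concentrations()].
#' @export
fsd_resolve <- function(mixture, cfg, calib_a, calib_b) {
  dec <- fsd(mixture, cfg)
  amps <- c(amplitude_at(dec, calib_a$wavelength),
            amplitude_at(dec, calib_b$wavelength))
  est <- c(predict_conc(calib_a, amps[1]), predict_conc(calib_b, amps[2]))
  names(est) <- c(calib_a$analyte, calib_b$analyte)
  resolved_concentrations("FSD", est,
    intermediates = list(deconvoluted_amplitudes = amps))
}

# branches: named list per analyte of list(config, divisor_unit, calibration)
ratio_branch_signal <- function(mixture, branch, derivative = FALSE) {
  cfg <- branch$config
  r <- ratio_spectrum(mixture, branch$divisor_unit,
                      cfg$divisor_concentration, cfg$divisor_floor)
  if (derivative) {
    d <- ratio_derivative(r, cfg$derivative_window, cfg$derivative_polyorder)
    amp <- amplitude_at(d, cfg$rdm_wavelength)
    if (is.na(amp))
      stop(sprintf("wavelength %g nm is masked in the derivative",
                   cfg$rdm_wavelength), call. = FALSE)
    list(signal = amp, n_masked = r$meta$n_masked)
  } else {
    list(signal = rdf_delta(r, cfg$rdf_pair[1], cfg$rdf_pair[2]),
         n_masked = r$meta$n_masked)
  }
}

#' Resolve a mixture by ratio-difference (RDF) or ratio-derivative (RDM)
#'
#' One branch per analyte: the mixture is divided by that branch's divisor
#' standard and the branch's read-off (amplitude difference for RDF,
#' derivative amplitude for RDM) is inverted through its calibration.
#'
#' @param mixture Mixture [uv_spectrum()].
#' @param branches List of branches, each a `list(config = , divisor_unit = ,
#'   calibration = )` with a [ratio_config()], the divisor's
#'   unit-concentration spectrum and the branch calibration.
#' @return A [resolved_concentrations()].
#' @export
rdf_resolve <- function(mixture, branches) {
  est <- numeric(0); inter <- list()
  for (br in branches) {
    sig <- ratio_branch_signal(mixture, br, derivative = FALSE)
    est[br$calibration$analyte] <- predict_conc(br$calibration, sig$signal)
    inter[[paste0("delta_p_", br$calibration$analyte)]] <- sig$signal
  }
  resolved_concentrations("RDF", est, intermediates = inter)
}

#' @rdname rdf_resolve
#' @export
rdm_resolve <- function(mixture, branches) {
  est <- numeric(0); inter <- list()
  for (br in branches) {
    sig <- ratio_branch_signal(mixture, br, derivative = TRUE)
    est[br$calibration$analyte] <- predict_conc(br$calibration, sig$signal)
    inter[[paste0("derivative_amplitude_",
                  br$calibration$analyte)]] <- sig$signal
  }
  resolved_concentrations("RDM", est, intermediates = inter)
}

#' Run all five resolution methods on one mixture
#'
#' Applies ACM, ISM, FSD, RDF and RDM, each through its calibrated suite
#' entry (see [calibrate_methods()]). A method whose entry is missing or
#' whose preconditions fail is reported as a structured failure; the other
#' methods still return.
#'
#' @param mixture Mixture [uv_spectrum()].
#' @param suite A `method_suite` from [calibrate_methods()].
#' @return Named list (`acm`, `ism`, `fsd`, `rdf`, `rdm`) of
#'   [resolved_concentrations()] or `method_failure` records.
#' @export
resolve_all <- function(mixture, suite) {
  run <- function(method, expr) {
    tryCatch(expr, error = function(e)
      structure(list(method = method, error = conditionMessage(e)),
                class = "method_failure"))
  }
  need <- function(entry, method) {
    if (is.null(entry)) stop(method, " is not calibrated", call. = FALSE)
    entry
  }
  list(
    acm = run("ACM", {
      e <- need(suite$acm, "ACM")
      acm_resolve(mixture, e$config, e$calib_interferent, e$calib_analyte,
                  noise_tol = e$noise_tol)
    }),
    ism = run("ISM", {
      e <- need(suite$ism, "ISM")
      ism_resolve(mixture, e$lambda_iso, e$calib_iso, e$calib_free)
    }),
    fsd = run("FSD", {
      e <- need(suite$fsd, "FSD")
      fsd_resolve(mixture, e$config, e$calib_a, e$calib_b)
    }),
    rdf = run("RDF", rdf_resolve(mixture, need(suite$rdf, "RDF"))),
    rdm = run("RDM", rdm_resolve(mixture, need(suite$rdm, "RDM")))
  )
}
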