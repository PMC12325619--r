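# Spectrum container, file I/O, resampling and amplitude read-off.
# Every downstream stage (simulation, the five resolution methods, the study
# pipeline) works on this one data structure.

WL_TOL <- 1e-9  # nm; tolerance for grid-step uniformity and span checks

#' UV absorption spectrum on a uniform wavelength grid
#'
#' A spectrum is a sampled absorbance curve: a strictly increasing,
#' uniformly spaced wavelength axis (nm) and one absorbance value (AU) per
#' wavelength, plus free-form metadata (analyte, concentration, solvent, ...).
#'
#' Absorbances must be finite; `NA` is allowed and marks a masked channel
#' (e.g. a wavelength excluded by the ratio-spectrum divisor floor, see
#' [ratio_spectrum()]). `NaN`/`Inf` are rejected.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing with a constant step (to within 1e-9 nm), length >= 2.
#' @param absorbances Numeric vector of absorbances in AU, same length.
#' @param meta Named list of free-form metadata.
#' @return An object of class `uv_spectrum` with fields `wavelengths`,
#'   `absorbances`, `meta`.
#' @examples
#' s <- uv_spectrum(c(250, 251), c(0.10, 0.20))
#' amplitude_at(s, 250.5)
#' @export
uv_spectrum <- function(wavelengths, absorbances, meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  absorbances <- as.numeric(absorbances)
  if (length(wavelengths) < 2)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (length(absorbances) != length(wavelengths))
    stop("wavelengths and absorbances differ in length", call. = FALSE)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite", call. = FALSE)
  d <- diff(wavelengths)
  if (any(d <= 0)) {
    row <- which(d <= 0)[1] + 1L
    stop("wavelengths not increasing at point ", row, call. = FALSE)
  }
  if (any(abs(d - d[1]) > WL_TOL)) {
    row <- which(abs(d - d[1]) > WL_TOL)[1] + 1L
    stop("non-uniform wavelength step at point ", row, call. = FALSE)
  }
  bad <- !is.na(absorbances) & !is.finite(absorbances)
  if (any(bad))
    stop("non-finite absorbance at point ", which(bad)[1], call. = FALSE)
  structure(list(wavelengths = wavelengths, absorbances = absorbances,
                 meta = meta),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  wl <- x$wavelengths
  cat(sprintf("<uv_spectrum> %d points, %.4g-%.4g nm, step %.4g nm\n",
              length(wl), wl[1], wl[length(wl)], wl[2] - wl[1]))
  n_mask <- sum(is.na(x$absorbances))
  if (n_mask > 0) cat("  masked channels:", n_mask, "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.uv_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, absorbance = x$absorbances)
}

#' Wavelength step of a spectrum (nm)
#' @param s A [uv_spectrum()].
#' @return Scalar step in nm.
#' @export
spectrum_step <- function(s) s$wavelengths[2] - s$wavelengths[1]

#' Uniform wavelength grid
#'
#' @param start,stop Grid limits in nm, `start < stop`.
#' @param step Grid pitch in nm, > 0; `(stop - start) / step` must be a whole
#'   number (to within 1e-6 of a step).
#' @return A `wavelength_grid` object.
#' @export
wavelength_grid <- function(start, stop, step) {
  if (!(start < stop)) stop("start must be < stop", call. = FALSE)
  if (!(step > 0)) stop("step must be > 0", call. = FALSE)
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-6)
    stop("(stop - start) / step is not a whole number", call. = FALSE)
  structure(list(start = start, stop = stop, step = step,
                 n = as.integer(round(n)) + 1L),
            class = "wavelength_grid")
}

#' Default working grid: 200-450 nm at 0.1 nm
#'
#' The source study does not state the instrument scan range or data pitch;
#' 200-450 nm covers every working wavelength (221-366 nm) and 0.1 nm
#' comfortably resolves the narrowest synthetic band (16 nm FWHM).
#' @return A [wavelength_grid()].
#' @export
default_grid <- function() wavelength_grid(200, 450, 0.1)

#' Wavelengths of a grid
#' @param g A [wavelength_grid()].
#' @return Numeric vector of wavelengths in nm.
#' @export
grid_wavelengths <- function(g) g$start + g$step * (seq_len(g$n) - 1L)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start, x$stop, x$step, x$n))
  invisible(x)
}

# ---- file I/O ----------------------------------------------------------

#' Read a spectrum from CSV
#'
#' File dialect: optional `#`-prefixed metadata lines (`# key: value`),
#' then a one-line header `wavelength_nm,absorbance`, then numeric rows.
#'
#' @param path Path to an existing CSV file.
#' @return A [uv_spectrum()]; parsed metadata ends up in `$meta`.
#' @seealso [write_spectrum_csv()] for the inverse; the round trip is
#'   lossless at full double precision.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0) {
      key <- trimws(substr(kv, 1, pos - 1))
      val <- trimws(substr(kv, pos + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 3)
    stop("expected a header plus at least 2 data rows", call. = FALSE)
  dat <- read.csv(text = body, header = TRUE, colClasses = "character")
  if (ncol(dat) < 2)
    stop("expected two columns: wavelength_nm,absorbance", call. = FALSE)
  wl <- suppressWarnings(as.numeric(dat[[1]]))
  ab <- suppressWarnings(as.numeric(dat[[2]]))
  bad <- which(is.na(wl) | is.na(ab))
  if (length(bad))
    stop("non-numeric cell at data row ", bad[1], call. = FALSE)
  d <- diff(wl)
  if (any(d <= 0))
    stop("wavelengths not increasing at data row ",
         which(d <= 0)[1] + 1L, call. = FALSE)
  if (any(abs(d - d[1]) > WL_TOL))
    stop("non-uniform wavelength step at data row ",
         which(abs(d - d[1]) > WL_TOL)[1] + 1L, call. = FALSE)
  uv_spectrum(wl, ab, meta)
}

#' Write a spectrum to CSV
#'
#' @param s A [uv_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  hdr <- character(0)
  for (key in names(s$meta)) {
    val <- s$meta[[key]]
    if (is.atomic(val) && length(val) == 1)
      hdr <- c(hdr, sprintf("# %s: %s", key, format(val, digits = 17)))
  }
  rows <- sprintf("%.17g,%.17g", s$wavelengths, s$absorbances)
  writeLines(c(hdr, "wavelength_nm,absorbance", rows), path)
  invisible(path)
}

# ---- interpolation -----------------------------------------------------

# Core linear interpolation with snapping to grid points (within WL_TOL) so
# that stored values are returned exactly where the query hits the grid.
interp_spectrum <- function(s, lambda) {
  wl <- s$wavelengths
  ab <- s$absorbances
  n <- length(wl)
  if (any(lambda < wl[1] - WL_TOL | lambda > wl[n] + WL_TOL))
    stop(sprintf("wavelength %.6g nm outside spectrum span [%g, %g]",
                 lambda[which(lambda < wl[1] - WL_TOL |
                              lambda > wl[n] + WL_TOL)[1]],
                 wl[1], wl[n]), call. = FALSE)
  lambda <- pmin(pmax(lambda, wl[1]), wl[n])
  i <- findInterval(lambda, wl)
  i <- pmin(pmax(i, 1L), n - 1L)
  step <- wl[2] - wl[1]
  w <- (lambda - wl[i]) / step
  out <- (1 - w) * ab[i] + w * ab[i + 1L]
  snap_lo <- abs(lambda - wl[i]) < WL_TOL
  snap_hi <- abs(lambda - wl[i + 1L]) < WL_TOL
  out[snap_lo] <- ab[i][snap_lo]
  out[snap_hi] <- ab[i + 1L][snap_hi]
  out
}

#' Absorbance at an arbitrary wavelength
#'
#' Linearly interpolated between the two bracketing grid points, so that
#' non-integer working wavelengths (e.g. 266.8 nm) are addressable on any
#' grid. Returns the stored value exactly when `lambda` is a grid point.
#' `NA` propagates from masked channels.
#'
#' @param s A [uv_spectrum()].
#' @param lambda Wavelength(s) in nm; must lie within the spectrum span.
#' @return Absorbance(s) in AU.
#' @export
amplitude_at <- function(s, lambda) interp_spectrum(s, lambda)

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; no extrapolation (the target grid must lie within
#' the source span). Exact at shared grid points, hence idempotent.
#'
#' @param s A [uv_spectrum()].
#' @param g A [wavelength_grid()] within the span of `s`.
#' @return A [uv_spectrum()] on `g` (metadata carried over).
#' @export
resample <- function(s, g) {
  wl_out <- grid_wavelengths(g)
  wl <- s$wavelengths
  if (wl_out[1] < wl[1] - WL_TOL || wl_out[length(wl_out)] > wl[length(wl)] + WL_TOL)
    stop("target grid extends beyond spectrum span; no extrapolation",
         call. = FALSE)
  uv_spectrum(wl_out, interp_spectrum(s, wl_out), s$meta)
}

# ---- peak diagnostics --------------------------------------------------

#' Wavelength of the spectrum maximum
#' @param s A [uv_spectrum()].
#' @return Wavelength (nm) of the largest absorbance.
#' @export
peak_wavelength <- function(s) s$wavelengths[which.max(s$absorbances)]

#' Measure the full width at half maximum of a single band
#'
#' Locates the global maximum and the two half-height crossings on either
#' side by linear interpolation. Intended for isolated bands (used to verify
#' solvent broadening and deconvolution narrowing numerically).
#'
#' @param s A [uv_spectrum()] containing one dominant band.
#' @return FWHM in nm.
#' @export
measure_fwhm <- function(s) {
  y <- s$absorbances
  wl <- s$wavelengths
  pk <- which.max(y)
  if (pk == 1L || pk == length(y))
    stop("band maximum lies on the grid edge; cannot measure FWHM",
         call. = FALSE)
  h <- y[pk] / 2
  left <- which(y[1:pk] <= h)
  right <- which(y[pk:length(y)] <= h)
  if (!length(left) || !length(right))
    stop("half-maximum level not crossed within the grid", call. = FALSE)
  i <- max(left)                       # last point below h on the left
  j <- pk + min(right) - 1L            # first point below h on the right
  step <- wl[2] - wl[1]
  xl <- wl[i] + step * (h - y[i]) / (y[i + 1L] - y[i])
  xr <- wl[j - 1L] + step * (h - y[j - 1L]) / (y[j] - y[j - 1L])
  xr - xl
}
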