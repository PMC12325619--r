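---
title: "Resolving a binary drug mixture from overlapping UV spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving a binary drug mixture from overlapping UV spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specmix)
```

## The problem

Hydrochlorothiazide (HCTZ) and triamterene (TRIM) are co-formulated in
fixed-dose diuretic tablets. Both absorb in the UV and their zero-order
spectra overlap below about 300 nm, so neither can be read directly at its
absorption maximum in a mixture. Chromatographic separation solves this at
the cost of solvents, energy and time; the alternative pursued here is
*spectral* resolution: mathematical transformations of the recorded spectra
that isolate one analyte's contribution at a time.

`specmix` implements five such methods behind one calibration/validation
pipeline, together with a synthetic-spectra generator so that every stage is
testable without instrument data. The key spectral facts the package builds
on: HCTZ shows maxima at 271 and 221 nm, TRIM's main band lies at 361 nm
where HCTZ does not absorb (a *zero-contribution point*), and the two unit
spectra in ethanol cross at an *isoabsorptive point* at 266.8 nm.

## The forward model

Spectra live on a uniform wavelength grid (default 200–450 nm at 0.1 nm).
Under the Beer–Lambert law a noiseless binary mixture is

$$A(\lambda) = c_H\,a_H(\lambda) + c_T\,a_T(\lambda) + \varepsilon(\lambda),
\qquad \varepsilon \sim \mathcal N(0, \sigma_\varepsilon^2)\ \text{i.i.d.},$$

with $a_i$ the unit-concentration absorptivity spectra (AU·mL/µg) and
concentrations in µg/mL. The generator builds $a_i$ as sums of Gaussian or
Lorentzian bands parameterized by center, FWHM and peak absorptivity.

The preset analyte models anchor what is anchorable:

* HCTZ: Gaussian bands at **271 nm** (peak absorptivity 0.0690, matching the
  published zero-order calibration slope at that wavelength) and **221 nm**;
* TRIM: main Gaussian band at **361 nm** (peak absorptivity 0.0803, again
  the published slope) plus short-wavelength bands at 258 and 290 nm.

Band widths and the short-wavelength TRIM amplitudes are *tuned constants*:
no molar absorptivities are published for this system, so they were chosen
once so that (i) the unit spectra cross at 266.8 nm (the preset geometry
lands at 266.81 nm, verified in the tests by a 0.001 nm brute-force scan),
(ii) TRIM's global maximum stays at 361 nm, (iii) HCTZ at 361 nm is
astronomically below 1% of its 271 nm value, and (iv) the ratio-spectrum
divisors stay above the masking floor across the 244–293 nm working regions.
The resulting isoabsorptive absorptivity (0.0570) happens to sit close to
the published 266.8 nm slope (0.0569), which was *not* fitted for.

The default noise level, `noise_sd = 0.002` AU (additive, homoscedastic),
puts synthetic replicate %RSDs in the 0.1–2.5% range typical of routine UV
assays. What the generator does **not** emulate: band asymmetry and vibronic
fine structure of real spectra, baseline drift, stray-light nonlinearity at
high absorbance, heteroscedastic (signal-proportional) noise, and excipient
background. Passing tests therefore demonstrate the *algebra and statistics*
of the methods under their stated assumptions, not instrument performance.

The solvent enters as a band-broadening multiplier (and optional shift):
stronger solute–solvent interaction broadens bands and worsens overlap. The
`rank_solvents()` rule mirrors the in-silico "greenness by design" decision:
exclude solvents with exothermic solvation for any analyte, then prefer the
weakest interaction with the analyte of interest (ties: lower dielectric
constant). The quantitative broadening mapping
`broadening_from_interaction()` is illustrative only — the underlying
relationship is known in direction, not in functional form.

## The five resolution methods

**Absorption correction (ACM).** TRIM is read directly at 361 nm. Its
contribution at 271 nm is removed with the correction factor
$F_{ac} = A_{TRIM}(271)/A_{TRIM}(361)$ measured on a pure TRIM standard
(concentration-independent under Beer–Lambert):
$A_{corr} = A(271) - F_{ac}\,A(361)$, then HCTZ's calibration is inverted on
$A_{corr}$. On noiseless synthetic mixtures this is exact to round-off, and
the tests assert it with a closed-form oracle.

**Isoabsorptive point (ISM).** At the crossing $\lambda_{iso}$ both analytes
share one absorptivity, so a calibration built from a *single* analyte there
reads the *total* concentration $c_H + c_T$. TRIM follows from 361 nm and
HCTZ by difference. The conservation $c_H = c_{tot} - c_T$ is structural;
accuracy lives entirely in the two calibrations. `find_isoabsorptive_point()`
locates the crossing by sign change plus linear interpolation; among multiple
crossings it returns the one with the largest local slope difference (and
reports all).

**Fourier self-deconvolution (FSD).** The measured spectrum is modelled as
the true spectrum convolved with a Lorentzian lineshape of half-width
$\sigma$, whose Fourier transform is $\exp(-\pi\sigma|x|)$ ($x$ in
cycles/nm). Deconvolution multiplies the transform by
$D(L,x)\,\exp(+\pi\sigma|x|)$, where the apodization $D$ (triangular by
default; boxcar and a $(1-(x/L)^2)^2$ taper are available) truncates the
exponentially amplified high-frequency noise at $|x| = L$. Bands narrow,
positions are preserved, and the operation is linear — so amplitude
read-offs on deconvoluted spectra calibrate linearly like any other signal.

Numerical choices: a linear baseline joining the record's endpoints is
subtracted before the FFT (zero-padding a non-zero edge would otherwise
inject amplified ringing), the record is zero-padded to the next power of
two, and the kernel is refused if $\exp(\pi\sigma L)$ would overflow. The
user-facing strength knob `nominal_fwhm` (default 90, the conventional
dialog value for this application) maps to
$\sigma = \texttt{nominal\_fwhm} \times \text{step}/2$, i.e. 4.5 nm on the
default grid; the vendor unit convention behind such dialog values is not
recoverable, so the mapping is the package's own documented choice, selected
by scanning the interference bias of the presets *before* any acceptance
measurement. With it, the residual overlap bias of the FSD read-off stays
below 1% across the mixture design.

For the synthetic presets the FSD read-offs default to 221 nm (HCTZ) and
361 nm (TRIM) — the wavelengths where the *other* component's deconvoluted
amplitude is negligible. Published work on the real system reads 299/366 nm;
those wavelengths are features of the measured spectra after deconvolution
and have no counterpart in the preset band geometry, so they are
configuration, not constants.

**Ratio difference (RDF).** Dividing the mixture by a divisor standard
($a_T \times 10$ µg/mL for HCTZ; $a_H \times 4$ µg/mL for TRIM) turns the
divisor analyte's contribution into a constant, which cancels exactly in the
amplitude difference $\Delta P = P(\lambda_1) - P(\lambda_2)$ (273/293 nm
for HCTZ, 244/274 nm for TRIM). $\Delta P$ is strictly proportional to the
other analyte's concentration. Channels where the divisor falls below
0.01 AU are masked rather than divided through — near-zero division is the
method's main numerical hazard.

**Ratio derivative (RDM).** The first derivative of the ratio spectrum
eliminates the constant instead; amplitudes at 283 nm (HCTZ) and 251 nm
(TRIM) are calibrated. The derivative is a Savitzky–Golay smoothing first
derivative, applied run-wise over contiguous unmasked segments so masks
never leak. The default window is **51 points** (5.1 nm at 0.1 nm pitch),
polynomial order 2. A narrow window (e.g. 9 points) is the textbook default
but is dominated by noise here: differentiation divides the per-channel
noise by the 0.1 nm step, and at 0.002 AU it leaves the 283 nm read-off with
calibration correlations near 0.99 rather than 0.999. Because the filter is
linear, widening it costs nothing structurally — linearity in concentration
and interferent invariance remain exact, which the tests assert at the 0.1%
level.

## Calibration, validation and the simulated study

`fit_calibration()` is ordinary least squares with Pearson `r`, residual SD
on $n-2$ degrees of freedom, and ICH-style limits
$LOD = 3.3\,\sigma_{resid}/|b|$, $LOQ = 10\,\sigma_{resid}/|b|$ (their ratio
is $10/3.3$ identically). The comparison layer provides the pooled-variance
Student t (Welch behind a flag), the variance-ratio F with the larger
variance in the numerator, both with critical values, and one-way ANOVA with
$\eta^2 = SS_{between}/SS_{total}$. All of these are delegated to the
standard R fitting machinery and cross-checked in the tests against
brute-force definitional sums.

`run_study()` binds everything into one deterministic simulated study:

* calibrations at 8 levels over 1–18 µg/mL (HCTZ) and 1–14 µg/mL (TRIM),
  ACM on 4–18 / 2–14 µg/mL, each level the mean of 3 determinations;
* the five-mixture design (4,6), (6,6), (4,12), (4,8), (8,6) µg/mL,
  found values averaged over triplicates;
* a dosage-form analogue at (4, 6) µg/mL compared against a simulated
  unbiased reference method (1% RSD) by t, F and ANOVA;
* standard addition at +2/+4/+6 µg/mL spikes;
* an illustrative greenness report.

These sizes keep a full study under a second while matching the published
design's replication structure; with the default noise level, mean
recoveries stay within 98–102% and every calibration keeps $r \ge 0.999$
across seeds (asserted over 20 seeds in the acceptance tests). Every random
draw flows from the single master seed, so a report re-runs bit-identically
from its recorded configuration; `write_study_report()` stamps each CSV with
the seed and a configuration digest.

Degenerate inputs are handled explicitly rather than silently: negative
concentration estimates are flagged, never clipped; a corrected absorbance
more than $3\sigma$ below zero flags the ACM result; masked wavelengths
refuse read-offs with an error; identical spectra make the isoabsorptive
search fail loudly; an all-constant ANOVA reports F as undefined.

## Known limitations

* FSD's single-wavelength read-off keeps a small residual-overlap bias
  (about −0.4% on the default design) that the four algebraic methods do not
  have; it is a property of single-point deconvolution read-offs, not a bug,
  and is why the noiseless-exactness guarantees cover ACM/ISM/RDF/RDM only.
* The AGREE/GAPI scorers reproduce the structure of the greenness metrics;
  the shipped example profiles are demonstrations. Principle-level inputs
  behind any published score are not recoverable from the final score, so no
  published greenness value is a package target.
* The generator's solvent model captures broadening direction only; do not
  read quantitative solvent physics into it.
* Two-component mixtures only; higher derivatives and multivariate (PLS/PCR)
  resolution are out of scope.

```{r example, eval = FALSE}
report <- run_study(study_config(seed = 1))
report$recovery_summary
write_study_report(report, "study-tables")
```
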