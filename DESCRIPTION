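Package: specmix
Title: Spectral Resolution of Binary Drug Mixtures from UV Absorption Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves two-component pharmaceutical mixtures from zero-order
    UV-Vis absorption spectra using five classical spectral-resolution methods:
    absorption correction, isoabsorptive-point quantitation, Fourier
    self-deconvolution, ratio-difference and first-derivative-of-ratio
    spectrophotometry. Includes ordinary-least-squares calibration with
    ICH Q2(R1)-style validation statistics (LOD/LOQ, recovery, precision,
    t/F comparison, one-way ANOVA with eta-squared), simplified AGREE and GAPI
    analytical-greenness scorers, a parametric synthetic-spectra generator that
    emulates the hydrochlorothiazide/triamterene system in ethanol, and an
    end-to-end simulated-study pipeline producing calibration, recovery and
    comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
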