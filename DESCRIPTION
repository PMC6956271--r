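Package: ocunano
Title: Analysis of Nanoparticle-in-Thermogel Ocular Drug Delivery Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for ocular drug-delivery studies of
    mucoadhesive polymeric nanoparticles dispersed in thermosensitive
    hydrogels. Provides reversible drug-nanoparticle binding inference from
    dynamic dialysis (log-linear donor-phase decay, membrane-constant
    calibration, free and bound drug fractions), three-phase drug mass
    balance from interrupted dialysis, Higuchi square-root-of-time release
    kinetics with slope comparison, DLS passive microrheology (Siegert
    inversion, mean-squared displacement, generalized Stokes-Einstein
    viscoelastic spectra) for mucoadhesion assessment, particle sizing from
    fluorescence micrographs by Gaussian FWHM fitting with bimodality
    detection, and sparse-sampling noncompartmental ocular pharmacokinetics
    (trapezoidal AUC with variance propagation and AUC comparison tests).
    A synthetic-data module generates every input with known ground truth so
    the full pipeline is testable without instrument or animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
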