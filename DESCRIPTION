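Package: CPMGcorrect
Title: Total Metabolite Concentrations from 1D 1H CPMG NMR via
    Linewidth-Based Correction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Protein binding attenuates metabolite signals in 1D 1H CPMG
    NMR spectra of proteinaceous specimens, so only free concentrations are
    measured directly. CPMGcorrect converts free concentrations into total
    (free plus protein-bound) concentrations using metabolite- and
    sample-specific correction factors derived from the protein-induced
    broadening of each signal. It provides the spectral measurement layer
    (polynomial baseline correction, full-width-at-half-maximum measurement,
    Lorentzian deconvolution, integration), shim correction against a
    non-binding reference signal, calibration of the loss-factor versus
    line-broadening relation, internal-standard quantification with a lower
    limit of quantification rule, Bland-Altman agreement statistics, and a
    physics-based simulator of CPMG spectra of partially protein-bound
    metabolite mixtures for validation without spectrometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectra-io.R'
    'peakfit.R'
    'correction.R'
    'quantify.R'
    'simulate.R'
    'fixtures.R'
    'pipeline.R'
    'evaluate.R'
    'cli.R'
    'zzz.R'
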