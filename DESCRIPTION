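Package: faintnmr
Title: Reference-Free Quantitative NMR from Absolute Signal Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification of analytes from 1D proton NMR spectra without an
    internal or external reference standard. Absolute signal integrals are
    normalized by the number of scans, the receiver gain, the proton count and
    the molar concentration to calibrate an intensity-gain (IG) factor; an
    empirical receiver-gain linearization corrects amplifier nonlinearity; and
    concentrations are back-calculated directly from absolute intensities.
    Includes a synthetic spectrum generator with the matching intensity model,
    a Bruker-style and an internal file format reader/writer, Fourier-transform
    processing with automated phase and baseline correction, region
    integration with signal-to-noise checks, ordinary-least-squares validation
    against prepared concentrations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
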