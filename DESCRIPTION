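Package: zfRaman
Title: Raman Spectral Fingerprinting of Zebrafish Organ Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolution of Raman spectra of zebrafish embryo and larva organs
    into damped-harmonic-oscillator bands (area, width, frequency descriptors),
    presence-based band retention across animals and developmental stages,
    per-organ partial least squares discriminant analysis (PLS-DA) over hours
    post-fertilisation, and scalar-projection / vector-module fingerprint
    statistics. Includes a synthetic spectrum generator reproducing the study
    design (six animals from two clutches, six organs, 24-168 hpf) so the whole
    chain is testable without instrument data, and a command-line pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    signal,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
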