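Package: anharmonicIR
Title: Anharmonic MIR/NIR Spectra Post-Processing: Overtones, Combination
    Bands, Band-Shape Synthesis and Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for anharmonic (VPT2-style) vibrational
    calculations of mid- and near-infrared spectra of molecular crystals.
    Classifies vibrational transitions into fundamentals, first overtones and
    binary combination bands; evaluates second-order anharmonic transition
    positions from harmonic wavenumbers and an anharmonicity-constant matrix;
    broadens discrete transitions into continuous spectra with Gauss-Lorentz
    product band shapes; decomposes regional integrated intensity by
    transition class; applies wavenumber-linear scaling (WLS) and ATR
    penetration-depth correction; matches experimental peaks to calculated
    transitions into assignment tables; and generates fully synthetic
    transition ledgers and noisy pseudo-experimental spectra with known
    ground truth for end-to-end validation. Ships curated band tables for
    crystalline menadione (vitamin K3) as a worked reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
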