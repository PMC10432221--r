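Package: micellesaxs
Title: SAXS Modeling of Surfactant Micelles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of small-angle X-ray scattering (SAXS) data from
    surfactant micelles such as polysorbate 20 and its ester fractions.
    Provides model-free analysis (Guinier fits, regularized indirect
    Fourier transform for the pair-distance distribution, Shannon channel
    counts, aggregation numbers), form-factor modeling and least-squares
    fitting of polydisperse core-shell ellipsoids of revolution, a
    quasiatomistic bead-level micelle builder on spherical Fibonacci
    lattices, Debye-equation scattering from bead models, non-negative
    least-squares decomposition of measured curves into candidate-model
    volume fractions, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
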