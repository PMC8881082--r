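Package: rellg
Title: Relative Expected Log-Likelihood Gain for Molecular Replacement Model Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diffraction-data-free, crystal-form-independent scoring of predicted
    protein models as molecular-replacement search models. Places a target
    structure and a predicted model in a common virtual cell, computes normalized
    structure factors, optimizes the model pose and an effective coordinate-error
    parameter against a phased complex-normal log-likelihood-gain, and accumulates
    a Fourier-shell-correlation-based expected LLG, normalized against an ideally
    imperfect model (complete model with 0.4 Angstrom radial RMS error). Includes
    coordinate-error B-factor weighting, a sequence-identity calibration of the
    score, and CASP-style null-model fitting and two-pass Z-score group ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
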