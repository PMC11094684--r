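Package: coilgel
Title: Coiled-Coil Hydrogel Design Search and Characterization Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Metropolis-style trimodal Monte Carlo search over coiled-coil
    protein sequences that minimizes terminal surface electrostatic-patch
    potentials (NEbcf/CEbcf) together with a stability score, behind a
    pluggable scorer contract with built-in screened-Coulomb and
    hydrophobicity surrogates. Companion analytics for hydrogel
    characterization: multiple-particle-tracking microrheology (mean-squared
    displacement, log-slope diagnostics, sigmoidal gel-point fitting,
    time-cure superposition with critical relaxation exponent), circular
    dichroism mean-residue ellipticity and 222/208 ratio, FTIR amide-I
    Gaussian deconvolution, UCST phase-boundary logistic regression, drug
    loading and withdrawal-corrected cumulative release mass balance, and
    caliper ellipsoid tumor volume. Includes seeded synthetic-data
    generators for particle trajectories, spectra, phase grids, and release
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
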