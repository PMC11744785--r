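Package: chirospec
Title: Electronic Circular Dichroism Spectra from Gaussian-Orbital
    Self-Consistent Field and Linear Response Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of electronic circular dichroism (ECD)
    spectra of molecules and QM/MM-embedded clusters with contracted Cartesian
    Gaussian atomic orbitals. Implements primitive-basis electron repulsion
    integrals by straight-line (unrolled) Obara-Saika evaluation plans up to
    d functions, Cauchy-Schwarz and density-weighted presorted screening for
    the Coulomb matrix, preselective (preLinK-style) screening for the
    exchange matrix, error-function-attenuated integrals for range-separated
    hybrid exchange, batched numerical exchange-correlation integration on a
    Becke-partitioned molecular grid, closed-shell SCF with DIIS, and linear
    response in both the generalized-eigenvalue and damped complex
    polarization propagator (CPP) formulations, from which velocity-gauge
    rotatory strengths and broadened Delta-epsilon spectra are assembled.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
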