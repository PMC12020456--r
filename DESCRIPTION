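Package: swigcpcm
Title: Gaussian-Switching Conductor-Like PCM Solvation with Dynamic Cavity Radii
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conductor-like polarizable continuum model (CPCM) for classical
    point-charge solutes with a smooth switching-Gaussian (SwiG) cavity
    discretization on Lebedev grids, dynamically scaled geometry-dependent
    cavity radii driven by electronegativity-equilibration charges and
    coordination numbers, and the complete analytical nuclear gradient of the
    polarization energy.  Includes a four-point finite-difference gradient
    oracle and potential-energy-surface continuity scans comparing isogrid
    and isodensity cavity schemes.
License: MIT
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
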