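Package: tke4d
Title: Turbulence Mapping and Regional Hemodynamics for 4D Flow MRI of the Thoracic Aorta
Version: 0.1.0
Authors@R:
    person("tke4d", "developers", email = "tke4d@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of 4D flow magnetic resonance imaging
    (MRI) turbulence mapping in the thoracic aorta. Generates synthetic
    phase-contrast datasets with known ground truth (pulsatile flow in a
    candy-cane aortic geometry, Gaussian intravoxel velocity distributions,
    phase wrapping, complex Gaussian noise), reconstructs velocity and
    turbulent kinetic energy (TKE) maps via phase-difference processing with
    temporal and 4D Laplacian phase unwrapping and a magnitude-ratio
    intravoxel velocity standard deviation estimator, computes regional
    hemodynamic parameters (average/maximum speed, total/maximum/median TKE)
    over the ascending aorta, aortic arch and descending aorta, and provides
    the paired rest-versus-stress statistical layer (normality-gated paired
    tests, post-hoc inter-region comparisons, linear regression against
    cardiac output, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
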