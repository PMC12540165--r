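Package: stenocfd
Title: Axisymmetric CFD Assessment of Intracranial Arterial Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics for intracranial
    atherosclerotic stenosis. Generates parametric axisymmetric stenotic
    vessel lumens that stand in for DSA- and CTA-segmented arteries,
    converts angiographic (TIMI frame count) and transcranial Doppler
    measurements into inlet boundary conditions, solves steady
    incompressible Newtonian flow with a finite-volume SIMPLE scheme,
    and derives translesional pressure ratio (PR), wall shear stress
    ratio (WSSR), and high-WSS area. Includes Murray cube-law outlet
    flow splitting, a hybrid CTA-geometry/DSA-flow (CMD) model,
    Bland-Altman and two-way random-effects ICC agreement statistics,
    and a seeded synthetic-cohort pipeline for modality-agreement
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
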