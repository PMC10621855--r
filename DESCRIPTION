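Package: pfafield
Title: Electric Field and Lesion Modeling for Cardiac Pulsed Field Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static modeling of the electric field around a focal
    pulsed field ablation (PFA) catheter in a layered, heterogeneous
    ventricular wall. Builds axisymmetric labeled tissue geometries
    (myocardium, fibrotic scar, intramyocardial and epicardial fat, blood,
    connective tissue), solves the nonlinear Laplace problem with a
    sigmoid field-dependent myocardial conductivity on a graded
    finite-element mesh, matches the applied voltage to a target delivered
    current, and extracts irreversible-electroporation lesion metrics
    (depth and surface width of the 1000 V/cm isoline), axis profiles and
    field hot/cold points around fat inclusions.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    EBImage,
    yaml,
    withr,
    stats,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
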