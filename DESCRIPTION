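Package: bivmech
Title: Biventricular Cardiac Mechanics on Idealized Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static finite-element simulation and personalisation of
    biventricular cardiac mechanics. Implements the reduced Holzapfel-Ogden
    passive law with active contraction and valve-annulus collagen stresses,
    a displacement/pressure P1 solver driven by cavity-volume and
    valve-centroid constraints via Lagrange multipliers, rule-based myocardial
    fibre fields, gamma-sweep estimation of passive anisotropy with
    literature-based pressure scaling, cine-label and valve-landmark quality
    control, and clinical/regional reporting (volumes, ejection fraction,
    wall thickness, AHA-segment fibre stress and stretch). A synthetic-geometry
    module generates idealized two-ellipsoid biventricular meshes and
    physiologically shaped volume, pressure and valve-motion traces so the
    whole pipeline runs without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
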