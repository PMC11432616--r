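Package: aosa
Title: Aorto-Septal Angle and Aortic Remodelling Morphometry from Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic morphometry of the thoracic aorta and left heart
    for studies of geometric remodelling after thoracic endovascular aortic
    repair (TEVAR). Ingests triangulated surface meshes (STL, PLY, OBJ, VTP)
    or NIfTI label volumes, solves a heat-conduction (Laplace) problem on the
    vessel wall to obtain equidistant isolines, and derives the vessel
    centerline, length, tortuosity index, equivalent diameter, and the outer
    and inner curvature-line lengths. Constructs the aortic and
    left-ventricular axes to measure the aorto-septal angle (AoSA) and the
    inclination of the ascending aorta, with seeded repeated measurements for
    repeatability analysis. A statistics layer provides the coefficient of
    variation, two-way random-effects intraclass correlation with confidence
    intervals, paired comparisons, percent change, and cohort summaries.
    Synthetic tube and two-chamber heart phantoms with closed-form geometry
    provide ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    xml2,
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
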