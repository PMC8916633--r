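Package: airwaymorph
Title: Centerline-Based Upper Airway Morphometry from CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic morphometry of the pharyngeal and subglottal airway
    from head/neck computed tomography. Reads CT volumes in Hounsfield units,
    harmonizes reconstruction kernels, segments the air lumen with an
    image-specific histogram-midpoint threshold, extracts a watertight lumen
    surface, smooths it by implicit Laplacian fairing, derives an
    arc-length-parameterized centerline by level-contour centroid extraction
    with B-spline smoothing, cuts cross-sections orthogonal to the centerline,
    partitions the airway into nasopharynx, oropharynx, laryngopharynx and
    subglottal regions from anatomic landmarks, and computes a 30-variable
    measurement record (region volumes, centerline lengths, boundary
    cross-sectional areas, anterior-posterior distances and widths, vocal tract
    length, velum length, piriform sinus lengths). Includes synthetic tubular
    CT phantoms with analytic ground truth for end-to-end validation, and a
    random-intercept mixed-effects growth analysis (likelihood-ratio age test,
    Wald sex contrasts, percent growth at age 5).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    RNifti,
    lme4,
    splines,
    stats,
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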