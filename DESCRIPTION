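Package: pocusalign
Title: Automatic Alignment of Paired Point-of-Care Ultrasound Bone Views
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic alignment of paired point-of-care ultrasound
    (POCUS) views of a pediatric forearm bone. Extracts anatomical landmarks
    (physis and diaphysis points) from segmented bone-boundary masks, estimates
    a flip-plus-rigid 2D transform by gradient-descent minimization of three
    anatomical constraints (physis alignment, diaphysis parallelism, bone-width
    spacing), fuses the two views into a lateral-radiograph-like overlay, and
    measures fracture angulation against the growth-plate perpendicular.
    Includes contour-distance evaluation metrics (directed Hausdorff, Chamfer),
    reader-study summary statistics, and a synthetic phantom generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
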