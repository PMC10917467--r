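Package: edhgeom
Title: Spherical-Cap Geometry of Epidural Hematomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric modelling of epidural hematomas (EDHs) as a pair of
    mirrored spherical caps inside a half-sphere model of the supratentorial
    brain. Computes cap height, predicted axial thickness and cranial-caudal
    extent from the hematoma's largest diameter and latitude, estimates volumes
    by the spherical-cap and ABC/ellipsoid methods, regenerates the guideline
    lookup table with surgical-evacuation thresholds (30 mL, 15 mm, 7 cm), and
    validates the model against voxelized phantoms via through-origin regression
    and paired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
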