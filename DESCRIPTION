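Package: megarray
Title: Forward-Model Evaluation of MEG Sensor Arrays for Deep and Folded Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate magnetoencephalography (MEG) sensor arrays by
    forward modeling, with emphasis on deep, highly folded source regions such
    as the cerebellar cortex. Provides synthetic head and source-surface
    geometry, analytic current-dipole fields in a spherically symmetric
    conductor, lead-field assembly for magnetometers, axial gradiometers and
    triaxial on-scalp sensors, scalp-projected and uniform (Laplace
    eigen-embedding plus farthest-point sampling) array layouts, sensitivity
    maps, principal-angle correlation maps between regional lead-field
    subspaces, and total Shannon information capacity with noise whitening and
    source-variance calibration. Results are returned as tidy tibbles with
    plotting and broom-style summary methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
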