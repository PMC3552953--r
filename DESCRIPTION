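Package: cliffscout
Title: Remote Identification and Assessment of Cliff Habitat from
    Elevation Models and Road-Based Viewsheds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for remotely identifying and assessing cliff habitat for
    cliff-nesting raptors such as the griffon vulture (Gyps fulvus) and the
    Egyptian vulture (Neophron percnopterus). Provides a raster elevation
    grid model with ESRI ASCII Grid I/O, Horn-method slope computation,
    exact line-of-sight viewsheds from road-based observers, slope-threshold
    cliff classification calibrated on occupied nesting cliffs, thematic-map
    accuracy assessment (confusion matrices, producer's and user's accuracy,
    omission and commission error, Cohen's kappa), a survey time/cost model
    comparing on-ground and street-level-imagery surveys, distance-based
    detectability analysis, and a seeded synthetic landscape generator so
    the whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
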