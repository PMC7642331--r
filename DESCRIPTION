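Package: roadcross
Title: Traversability and Collision Risk of Roads for Large Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the traversability of roads for large mammals under
    heterogeneous traffic: a Poisson-headway collision-probability model
    (coincidence time, probability of successful crossing and of
    animal-vehicle collision), allometric maximum running speeds from body
    mass, a single-link heterogeneous traffic-flow microsimulator reporting
    harmonic mean flow speeds, threshold (barrier) traffic volumes, crossing
    exposure, Latin hypercube sensitivity analysis with bootstrap partial
    inclination coefficients, circular (von Mises kernel) activity densities
    with the Dhat1 overlap coefficient, and activity-weighted hourly
    collision risk. Includes synthetic generators for traffic profiles and
    camera-trap capture records so the full pipeline runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
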