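Package: lumovar
Title: Variability and Local Dynamic Stability of Lumbar Movement Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for repetitive lumbar movement recordings:
    converts three-marker cluster trajectories of the thorax (T8) and pelvis
    (S1) into relative lumbar Euler angles, segments trials into reaching
    cycles, and quantifies movement patterns by spatial variability (MeanSD),
    temporal variability (CyclSD), range of motion, movement velocity, and
    local dynamic stability via the local divergence exponent computed from a
    delay-embedded state space. Includes a synthetic-data generator for
    angle-level trials, marker-level trials, and whole cohorts with known
    ground-truth noise and effect parameters, and a statistics stage with
    three-way mixed MANOVA (threat condition x low-back-pain group x expected
    back strain), univariate follow-ups with partial eta squared, and
    nonparametric descriptive tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
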