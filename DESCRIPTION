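Package: codatime
Title: Compositional Analysis of 24-Hour Time Use and Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the 24-hour time-use composition of
    sleep, sedentary behaviour, light physical activity and
    moderate-to-vigorous physical activity relates to cognitive outcomes
    in older adults. Provides simplex mathematics (closure, isometric
    log-ratio pivot coordinates, compositional means, ternary
    coordinates), accelerometry epoch processing with non-wear detection
    and cut-point classification, cognitive composite construction,
    compositional linear regression with behaviour-context moderators,
    marginality-respecting type II F-tests with backward selection and
    Benjamini-Hochberg false discovery rate adjustment, one-for-remaining
    time-reallocation prediction curves, and a synthetic-cohort generator
    for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
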