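Package: vegrisk
Title: Pesticide Residue Risk Indices for Vegetable Surveillance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring pesticide residue risk from regulatory
    vegetable inspection records. Cleans and harmonizes sampling tables,
    matches detections against maximum residue limits (MRLs), scores each
    sampled batch with a worst-case hazard quotient, and combines the
    exceedance probability P with the mean hazard severity S into the risk
    index IR = P x S at the province-by-vegetable, vegetable, and province
    levels, with threshold classification against IR0 = 0.02. Also tracks
    the risk-weighted spatial center of gravity across years (transfer
    distance and bearing), and ships a seeded synthetic surveillance
    generator so the whole pipeline is testable without access to a real
    supervision database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
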