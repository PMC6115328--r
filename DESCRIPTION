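Package: snakevuln
Title: Mapping Populations Vulnerable to Snakebite Envenoming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for global snakebite-vulnerability
    mapping. Refines expert-opinion snake range maps with occurrence records
    via multivariate environmental similarity surfaces (MESS), stacks
    species ranges into richness layers stratified by WHO medical category
    and antivenom availability, and triangulates them with Healthcare
    Access and Quality (HAQ) Index deciles and travel-time accessibility to
    enumerate vulnerable populations per administrative unit. Includes a
    synthetic-data generator with brute-force oracles so the full pipeline
    is testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    geosphere,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
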