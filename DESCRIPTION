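Package: gazentropy
Title: Markov-Chain Gaze Entropy Analysis of Eye-Tracking Scanpaths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying visual attention from eye-tracker fixation
    exports. Fixations are assigned to named areas of interest (AOIs) by
    polygon containment, dwell-time proportions are computed per area, and
    each trial's AOI sequence is modelled as a first-order Markov chain from
    which transition entropy (Ht) and stationary entropy (Hs) are computed in
    bits. Group-level comparison across experimental conditions is provided
    via balanced two-way ANOVA with partial eta squared and pairwise
    dominance percentages, together with a seeded synthetic scanpath
    generator emulating a multi-condition driving-simulator cohort so that
    every stage of the pipeline is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
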