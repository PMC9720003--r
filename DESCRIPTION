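Package: plasmidstab
Title: Segregational Stability and Optimal Copy Number of Multicopy Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the serial-dilution population dynamics of bacteria
    carrying a nontransmissible multicopy plasmid. Provides the deterministic
    day-to-day map for the plasmid-bearing fraction under segregational loss,
    fitness cost and antibiotic pulses, the within-day two-type branching
    process that links measurable growth parameters to the interday model,
    estimators that recover model parameters from plate-reader growth curves
    and one-day competition experiments, generators for synthetic experiments
    with known ground truth, and stability analyses (time to extinction,
    persistence scores, minimum selective pressure, optimal plasmid copy
    number) under constant, periodic and random drug-exposure regimes.
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
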