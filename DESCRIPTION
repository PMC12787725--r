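Package: paddyrisk
Title: Soil-Rice Heavy-Metal Pollution, Ecological and Human Health Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of heavy-metal contamination in paddy soil-rice
    systems. Computes bioconcentration and translocation factors across rice
    growth stages, single-metal and Nemerow composite pollution indices,
    Hakanson single-metal and integrated potential ecological risk indices,
    four-pathway (rice consumption, soil ingestion, inhalation, dermal
    contact) non-carcinogenic and carcinogenic human health risk for adult
    and child populations, and Monte Carlo propagation of parameter
    uncertainty to exceedance probabilities. Includes a calibrated synthetic
    data generator for soil, plant tissue and phytotoxicity endpoint tables,
    and a reproducible end-to-end pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
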