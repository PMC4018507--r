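Package: crcaware
Title: Cost-Effectiveness Modelling of a Colorectal Cancer Awareness Campaign
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A discrete-time state-transition cohort model of colorectal
    cancer natural history (adenoma-carcinoma sequence through Dukes'
    stages), overlaid with the biennial gFOBT screening programme and an
    awareness-campaign intervention that transiently raises symptomatic
    presentation rates. Provides health-economic evaluation (discounted
    costs, life-years, QALYs, ICER, net monetary benefit), deterministic
    and probabilistic sensitivity analyses, a screening-uptake equivalence
    search, and the interrupted time-series statistics used to quantify a
    short-term step change in monthly cancer incidence. Synthetic fixtures
    (demography, all-cause mortality, stage-specific survival, pilot-style
    monthly count series) make the full pipeline runnable and testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
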