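Package: snapcea
Title: Microsimulation of Food Incentive and Disincentive Policies in SNAP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level state-transition microsimulation of cardiometabolic
    health outcomes, costs, and cost-effectiveness of food incentive,
    disincentive, and restriction scenarios in the US Supplemental Nutrition
    Assistance Program (SNAP). Includes a weighted synthetic SNAP adult
    population generator (Gaussian copula over cardiometabolic risk factors),
    conversion of price instruments into overall dietary intake changes,
    log-linear diet-disease relative risks with age attenuation and mediated
    (BMI, blood pressure) pathways, an annual-cycle cardiovascular disease and
    diabetes simulation engine with common random numbers, discounted QALY and
    cost accrual, incremental cost-effectiveness analysis from societal and
    government-affordability perspectives, and probabilistic sensitivity
    analysis with cost-effectiveness plane summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
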