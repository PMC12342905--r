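Package: cvdcoi
Title: Cost-of-Illness Modelling of Cardiovascular Disease in the UK
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for prevalence-based
    cost-of-illness analysis of cardiovascular disease in the United
    Kingdom. Provides a penny-exact cost ledger with inflation,
    discounting and currency conversion; top-down apportionment rules
    for attributing aggregate NHS spending to cardiovascular disease; a
    Markov cohort model of post-stroke long-term care; an informal-care
    cost model driven by average marginal effects from logistic and
    ordered-logistic regression on survey microdata; human-capital
    production-loss models for premature mortality and morbidity; and
    generic one-way (tornado) and probabilistic (Monte Carlo)
    sensitivity analysis. Ships published national cost tables as
    packaged fixtures and synthetic-data generators that emulate the
    survey, audit and labour-market sources so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
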