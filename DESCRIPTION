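Package: mskecon
Title: Indirect Economic Implications of Musculoskeletal Activity Limitations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the indirect economic burden of
    musculoskeletal (MSK) activity limitations and the economic benefits of
    treatments that restore physical function. Provides a synthetic
    generator for NHIS-style survey microdata with eight 5-level activity
    limitation items and four economic outcomes; an SF-36 proxy Physical
    Function Index built from five weighted limitation items; survey
    preprocessing (income band midpoints, CPI adjustment, missed-work-day
    capping, design-matrix expansion); logistic, least-squares and
    negative-binomial outcome models under a full per-item specification and
    an index specification; an odds-ratio scenario engine for predicting
    outcomes of covariate profiles; and a translator from published SF-36
    physical-function improvements after hip and knee replacement to
    employment, income, absenteeism and disability-payment deltas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
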