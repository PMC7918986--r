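Package: pumprisk
Title: Probabilistic Benzene Cancer Risk Assessment for Gasoline Fueling
    Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Consumer and occupational probabilistic cancer risk assessment
    of benzene exposure at commercial gasoline stations. Provides quality
    control and geometric summarization of personal whole-air canister
    samples (including limit-of-detection substitution and fill-time
    estimation from canister vacuum decay), parameterization and sampling
    of exposure-factor distributions (lognormal concentration,
    truncated-normal fill time, zero-truncated Poisson fill frequency),
    Monte Carlo simulation of excess lifetime cancer risk from an
    inhalation unit risk, and contextualization of pumping risk against
    census-tract ambient benzene cancer risk. A synthetic-data generator
    emulates the sampling design so the full pipeline runs reproducibly
    without access to the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
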