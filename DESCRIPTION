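Package: ectogradient
Title: Mechanistic Life-History Modelling of Lizards Along Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale mechanistic niche modelling for a pair of elevationally
    segregated lacertid lizards (Podarcis muralis and Iberolacerta horvathi).
    Generates synthetic hourly site microclimates with elevational structure
    (temperature lapse, humidity increase, snow season), computes operative
    temperatures and behavioural thermoregulation across shade levels and
    substrate retreat depths, couples body temperature to a standard Dynamic
    Energy Budget (DEB) life cycle, estimates DEB parameters from zero-variate
    life-history data by the covariation method (symmetric loss, MRE/SMSE), and
    compares the six extracted life-history traits across elevation, species
    and syntopy/allotopy with OLS regressions, AICc model selection and
    Tukey-Kramer post hoc contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    multcomp
Config/testthat/edition: 3
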