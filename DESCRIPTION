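Package: hibernage
Title: Epigenetic Ageing Across Hibernation Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how hibernation shapes epigenetic ageing in
    seasonally sampled wild mammals. Implements the epigenetic pacemaker
    (alternating least-squares estimation of a latent epigenetic state from
    CpG methylation), an elastic-net epigenetic clock with grouped holdout
    prediction, generalized additive mixed models with cyclic cubic splines
    for circannual effects, simulation-based power and type-I error
    estimation for seasonal terms, active-versus-hibernation ageing-rate
    contrasts, and per-CpG association scans with multiplicity control.
    A synthetic-data generator reproduces the longitudinal, active-season
    restricted sampling design of a wild hibernator study so that every
    stage of the analysis is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
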