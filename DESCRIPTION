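Package: usualintake
Title: Usual Dietary Intake Distributions from Single 24-Hour Recalls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates population distributions of usual intake of
    nearly-daily consumed foods and nutrients from 24-hour dietary recall
    data. Implements a one-day method that combines a Box-Cox
    measurement-error model fitted to a single recall per person with an
    external within-person to between-person variance ratio, alongside an
    amount-only mixed-model fitter for replicate-recall data. Includes
    survey-weighted percentile and prevalence estimation below a cutoff
    (EAR cut-point), balanced repeated replication standard errors,
    two-one-sided-test equivalence comparisons between methods, a
    variance-ratio sensitivity sweep, and a synthetic recall-data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    pracma,
    optparse
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
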