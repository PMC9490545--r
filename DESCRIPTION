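Package: auditflow
Title: Clinical Workflow Measurement from EHR Audit Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs outpatient encounter workflow time points from
    electronic health record (EHR) audit-log event streams, calibrates and
    imputes unobservable "black hole" intervals (such as a physician entering
    the examination room before logging in) from time-motion observations,
    validates audit-derived times against direct observation, and estimates
    the effect of a point-of-care tool on encounter efficiency with two-level
    propensity-score greedy matching and matched-cluster linear mixed models.
    Includes a seeded discrete-event clinic-day simulator that produces
    ground-truth timelines, audit events, time-motion records and metadata
    for end-to-end method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lme4,
    sandwich,
    glmnet,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
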