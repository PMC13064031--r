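Package: mcikit
Title: Evaluation Toolkit for Hospital Mass-Casualty-Incident Exercises
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytics for full-scale hospital mass-casualty-incident (MCI)
    exercises instrumented with an indoor real-time location system (RTLS).
    Turns raw tag position streams into geofence occupancy episodes, dwell
    times and staff-patient proximity contacts; evaluates two-stage triage
    accuracy (under-/overtriage against expected vignette categories) and
    triage durations; scores NASA-TLX workload and TEAM teamwork
    questionnaires; and runs the accompanying statistical pipeline (normality
    gate, parametric/non-parametric two- and k-group tests, Hedges' g effect
    sizes with confidence intervals). A synthetic-exercise generator
    reproduces the statistical structure of a benchmark exercise so the whole
    pipeline can be exercised and validated without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
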