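Package: stopsignal
Title: Simulation and Analysis of Adaptive Stop-Signal Task Experiments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing adaptive stop-signal
    task (SST) experiments. Provides a session designer with a 1-up/1-down
    stop-signal delay staircase, an independent horse-race simulator of
    trial-level behaviour with ex-Gaussian go latencies and covariate-linked
    participant profiles, the nonparametric integration-method estimator of the
    stop-signal reaction time (SSRT) with replacement of go omissions,
    consensus participant-level quality control, and cohort-level statistics:
    linear mixed-effects models of go reaction time and SSRT, BMI-SSRT
    correlations with outlier sensitivity, and exact a-priori power analysis
    for correlation tests. All stages read and write plain CSV/JSON schemas and
    are reproducible from a configuration object and a seed.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'analysis.R'
    'cli.R'
    'io.R'
    'power.R'
    'qc.R'
    'race_sim.R'
    'ssrt.R'
    'stopsignal-package.R'
    'task_design.R'
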