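Package: edflow
Title: Discrete-Event Simulation of Low-Acuity Pediatric Emergency
    Department Patient Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-event simulation of the journey of low-acuity
    (Emergency Severity Index 4 and 5) patients through a pediatric
    emergency department, with resource contention for rooms, nurses and
    providers. Implements the service-time distribution families and
    non-homogeneous Poisson arrival process used in ED flow modelling,
    the Achievable Benchmark of Care (pared-mean) computation for
    provider diagnostic-testing rates, replication-based inference with
    pooled-variance t intervals, what-if testing-rate scenario
    experiments, resource calibration, provider impact reports, and
    synthetic-data generators that stand in for institutional
    administrative extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
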