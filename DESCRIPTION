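Package: erpactr
Title: Vincentized ERP Selective-Set Analysis and ACT-R Forward Simulation
Version: 0.1.0
Authors@R: person("ERP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for go/no-go target-detection ERP experiments on
    a 12-channel 10-20 montage: vincentized quantile-bin statistics, split-plot
    omnibus ANOVA with focused Bonferroni contrasts and a minimum-significant
    amplitude-difference threshold, target/distractor enhancement
    classification with a continuity-corrected chi-square proportion test,
    neural activity-path construction under wiring-minimization movement
    constraints, a current-dipole spherical-head forward model with triangular
    spike time courses, a minimal ACT-R production-cycle simulator with
    polyspiking and coarse-coded topographic maps, and structural/functional
    homology tests (z-scored localization ranges, per-bin map regressions).
    Includes a seeded synthetic-data generator for trial sequences, behavior
    and multi-subject epoched ERPs so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
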