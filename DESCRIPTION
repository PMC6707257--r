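Package: ctlsim
Title: Agent-Based Simulation of Cytotoxic T Lymphocyte Killing of Tumor Cells
Version: 0.1.0
Authors@R:
    person("ctlsim", "developers", email = "ctlsim@example.org", role = c("aut", "cre"))
Description: Off-lattice agent-based simulator of co-cultures of human cytotoxic
    T lymphocytes (CTL) and tumor target cells in a virtual culture well. Cells
    interact through mass-spring-damper adhesion and soft repulsion; target
    cells cycle, divide and defend against attacking CTL, and CTL are subject
    to probabilistic inactivation near defending targets. The package provides
    killing-assay scenarios across effector-to-target ratios, per-capita
    killing statistics, optimal-ratio sweeps, prolonged (multi-day) co-culture
    runs, sequential effector-dosing comparisons with rank-sum testing, and a
    grid-search calibration of the inactivation parameters against reference
    killing curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
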