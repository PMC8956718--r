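Package: oncohit
Title: Minimum Hitting-Set Selection of Combination Therapy Targets from
    Single-Cell Tumor Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects minimum-size combinations of cell-surface receptor gene
    targets from per-patient single-cell expression matrices of tumor and
    non-tumor cells. A gene is considered able to kill a cell when the cell
    expresses it at least r times the mean non-zero expression observed in
    the patient's non-tumor cells, turning target selection into a
    constrained minimum hitting-set problem: kill at least a fraction lb of
    tumor cells while killing at most a fraction ub of non-tumor cells.
    Provides proven-optimal per-patient solutions (individual target sets),
    fairness-constrained cohort-level solutions in which no patient receives
    more than alpha targets beyond their individual optimum (cohort target
    sets), alternative-optima enumeration with gene frequency and
    co-occurrence statistics, a greedy baseline, replicate sampling,
    normal-tissue expression filtering, and synthetic cohort generators with
    planted ground truth. The exact solvers use a specialized
    branch-and-bound search implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
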