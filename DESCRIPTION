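Package: ufbar
Title: Unsteady-State Flux Balance Analysis for Time-Course Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrates time-course absolute-quantitative metabolomics with
    constraint-based metabolic models to predict intracellular flux states of
    dynamic systems (unsteady-state flux balance analysis, uFBA). Provides
    k-nearest-neighbour imputation and PCA-based discretization of metabolite
    trajectories into linearized metabolic states, ordinary-least-squares rate
    estimation with confidence intervals, construction of closed-system
    unsteady models and matched steady-state FBA controls, a parsimonious
    metabolite-node relaxation algorithm (MILP, LP and QP formulations with
    integer-cut enumeration of alternative optima), flux variability analysis,
    artificial-centering hit-and-run flux sampling, flux-state comparison
    statistics, and single-gene essentiality simulation. Includes generators
    for synthetic toy networks and ground-truth time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    quadprog,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
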