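Package: fluxsum
Title: Flux-Sum Analysis for Metabolite-Centric Strain Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identifies metabolite targets for microbial strain improvement by
    flux-sum analysis of constraint-based metabolic models. The flux-sum of a
    metabolite is half the summed absolute rate of all reactions producing or
    consuming it at steady state; attenuating or intensifying it between its
    wild-type value and its feasible extremum can force a desired change in
    by-product secretion while guaranteeing a stated growth level. The package
    reads genome-scale models (community JSON dialect and an SBML Level 3 FBC
    subset), performs flux balance analysis and lexicographic two-step solves,
    linearizes the flux-sum with big-M indicator constraints, scans all internal
    metabolites over an attenuation/intensification grid, and reports worst-case
    target production with growth guarantees. Ships a self-contained
    bounded-variable simplex and branch-and-bound solver, programmatic toy
    fermentation networks, tidy result tables and ggplot2 profile plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    xml2,
    readr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
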