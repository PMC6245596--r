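Package: fluxpen
Title: Frequency-Penalized Linear-Programming Extraction of Elementary Flux Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of pathways and Elementary Flux Modes (EFMs) from
    stoichiometric metabolic networks by repeated linear programming with
    random positive seeds. The objective function is dynamically penalized
    with weights w = 1 + p*F derived from the running frequency F of each
    reaction in the solutions obtained so far, which discourages (without
    forbidding) over-represented reactions and improves the
    representativeness and diversity of the extracted set. Includes readers
    for SBML, COBRA-JSON and a TSV stoichiometric-matrix dialect,
    reversible-reaction splitting, a brute-force EFM oracle for small
    networks, rank-based elementarity testing, and statistical comparison of
    extraction experiments (Wilcoxon signed-rank test, chi-bar-squared
    divergence).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
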