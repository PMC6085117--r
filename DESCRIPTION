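Package: pancmorph
Title: Stochastic Branching Morphogenesis and Clonal Statistics for the
    Developing Pancreas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the large-scale organization of branched
    ductal organs such as the embryonic pancreas. Implements a
    branching-annihilating random walk model of ductal morphogenesis in
    which active termini elongate, bifurcate stochastically, and terminate
    irreversibly on proximity to neighbouring ducts; a neutral-drift model
    of precursor segregation and duplication at ductal termini leading to
    monoclonal conversion along branch generations, with inference of the
    precursor pool size; clone-level statistics for multicolour
    (confetti-style) lineage tracing data, including potency
    classification, mean-rescaled cumulative size distributions,
    quantile-quantile comparison, exact and asymptotic rank tests, and a
    bootstrap assessment of clonality from spatial same-colour pair
    probabilities; and a synthetic clone-table generator used as a
    ground-truth harness for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
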