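Package: ebca
Title: Expert-Based Cooperative Analysis for Health-System Benchmarking and Case-Mix
Version: 0.1.0
Authors@R:
    person("EbCA", "Maintainers", email = "tools@example.org", role = c("aut", "cre"))
Description: Toolkit for expert-based cooperative analysis of health-care
    systems: a formal prior knowledge base of if-then rules that guides two
    analysis engines. The first engine is Monte-Carlo stochastic Data
    Envelopment Analysis for benchmarking decision-making units (e.g. small
    health areas) whose inputs and outputs are known only through
    expert-elicited probability models. The second is rule-guided hierarchical
    clustering for case-mix discovery in mixed numeric/categorical data, using
    reciprocal-nearest-neighbour Ward agglomeration under a mixed
    dissimilarity and Calinski-Harabasz cut selection. Interpretation-support
    tools (per-variable significance tests, class panel graphs, marked cells,
    inconsistency detection) and expert-agreement statistics (Cohen's kappa,
    consistency ICC, diagnostic metrics) close the iterative
    knowledge-elicitation loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ape,
    clue,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
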