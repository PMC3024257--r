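Package: coexmod
Title: Transcription Module Discovery and Case/Control Dysregulation Analysis
Version: 0.9.0
Authors@R:
    person("Analysis", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers potentially overlapping transcription modules
    (biclusters) in multi-dataset expression compendia with the Iterative
    Signature Algorithm, corrects dataset batch effects with parametric
    empirical-Bayes location/scale adjustment, scores modules for
    case/control dysregulation with weighted sample scores, Welch t-tests
    and label-permutation validation, organizes modules into a
    subset-relation hierarchy, computes hypergeometric functional
    enrichment against GMT gene sets, and analyzes the interaction network
    of genes recurring across dysregulated modules (random-subnetwork
    nulls, degree and PageRank comparisons, hierarchical random graph
    fitting with degree-preserving rewired nulls). Includes a synthetic
    data generator with planted modules, batch effects and hemizygous gene
    dosage so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
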