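Package: dtrinet
Title: Experiment-Level Curation Analytics for Direct Transcriptional
    Regulatory Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Data model, validation and analysis pipeline for experiment-level
    literature curation of direct transcriptional regulatory interactions
    (DTRIs). Provides controlled-vocabulary record handling with ortholog
    mapping and binding-site proximity classification, aggregation of
    experiment records into unique TF-target interactions with evidence,
    species, context and mode summaries, candidate-paper corpus coverage and
    overlap statistics, directed-network connectivity statistics with a
    degree-preserving rewiring null, benchmarking of curated target sets
    against TF-perturbation differential-expression screens (hypergeometric
    overrepresentation, rank-based AUROC with bootstrap confidence intervals,
    consensus rank aggregation), and a synthetic-data generator with known
    ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
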