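Package: harmscore
Title: Harmfulness Scores for Microplastic Polymers from Literature Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite Harmfulness Scores for microplastic polymers from
    bibliographic abstract corpora. Reads CSV/RIS/BibTeX records, tags documents
    against controlled vocabularies (polymers, engineered nanoparticles,
    morphologies, impact descriptors, techniques, countries), scores sentiment
    with a rule-based valence lexicon, builds term co-occurrence networks with
    link strengths and centralities, fits multimodal particle-size distributions
    as composite Gaussian envelopes, clusters the corpus into themes, and
    aggregates per-polymer sentiment, impact, and centrality components into a
    frequency-weighted, confidence-penalized risk score with bootstrap and
    leave-one-out diagnostics. Includes a synthetic-corpus generator with
    controlled entity frequencies and sentiment mixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    stringi,
    igraph,
    Matrix,
    cluster,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    e1071,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
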