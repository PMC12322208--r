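Package: radalign
Title: Guideline-Aligned Evaluation of Language-Model Imaging Recommendations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well free-text clinical one-liners can be
    mapped to American College of Radiology (ACR) Appropriateness Criteria
    Topics by a pluggable text-completion backend, and for turning predicted
    Topics into imaging-study recommendations by deterministic lookup in a
    versioned guideline knowledge base. Includes the retrieval machinery used
    to build prompt context (Okapi BM25, cosine-similarity embedding ranking,
    uniform random retrieval, fixed-width corpus chunking), prompt construction
    and answer parsing for baseline, chain-of-thought, in-context-learning and
    retrieval-augmented strategies, a multi-seed benchmark runner, the
    set-based imaging-appropriateness metric suite (imaging accuracy,
    unnecessary- and missed-imaging rates, F1, Dice-Sorensen overlap), and a
    linear-probability-model analysis of prospective reader studies with
    question fixed effects and two-way cluster-robust standard errors.
    Synthetic generators provide miniature knowledge bases, labeled one-liner
    datasets, confusion-driven mock backends and participant-by-question
    response grids for fully offline, deterministic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
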