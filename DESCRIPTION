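Package: crsignature
Title: Tissue-Independent Transcriptomic Signatures of Calorie Restriction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for deriving a
    tissue-independent transcriptomic signature of long-term calorie
    restriction from bulk RNA-seq counts across multiple neuroendocrine
    tissues. Provides negative-binomial Wald differential expression per
    tissue with Benjamini-Hochberg correction, FPKM normalisation with
    low-expression filtering, an ensemble of seven attribute-weighting
    (feature-selection) models (information gain, gain ratio, chi-squared,
    Gini index, symmetric uncertainty, ReliefF, and a OneR-style rule
    scorer) with min-max normalised weights, sum-of-weights signature
    ranking with a tissue-independence diagnostic, posterior-draw effect
    reporting (median, highest density interval, probability of direction,
    and region-of-practical-equivalence proportion), and correlation-matrix
    PCA with percent-similarity hierarchical clustering. A seeded synthetic
    count generator emulating a two-diet by four-tissue design with planted
    effects makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
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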