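Package: dtmtox
Title: Dynamic Topic Models for Time-Course Toxicogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters compound-by-time differential expression signatures with
    a Dynamic Topic Model (DTM). Treated-versus-control contrasts are encoded
    as a time-sliced bag-of-words corpus in which each differentially
    expressed gene contributes a direction-tagged word ("Gene_up"/"Gene_down")
    whose count is 100 times its linear fold change. Topics -- probability
    distributions over gene-words that drift across time slices through a
    Gaussian random walk on natural parameters -- are fitted by variational
    EM with a variational Kalman smoother, and interpreted through hard
    sample assignment, per-slice gene rankings, representative gene sets and
    Fisher's exact gene-set enrichment. Seed-deterministic simulators for
    both DTM corpora and repeated-dose expression studies with planted
    mode-of-action modules support end-to-end recovery benchmarking without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
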