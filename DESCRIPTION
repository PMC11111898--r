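Package: avsin
Title: Phoneme-Level Analysis of Audiovisual Speech-in-Noise Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring and analysing word-identification experiments in
    which noisy auditory words are paired with real or synthetic talking faces.
    Typed responses are scored at the word level (exact match, homophones,
    curated misspellings) and at the phoneme level (multiset Jaccard overlap of
    ARPAbet phonemizations from a CMU-format pronouncing lexicon). The package
    decomposes accuracy by phoneme and face type, fits mixed-effects condition
    models, fits a logistic phoneme-presence model of word accuracy supporting
    counterfactual coefficient substitution, performs prevalence-weighted corpus
    extrapolation and paired-t power analysis, and simulates complete
    counterbalanced experiments from a viseme-transmission generative model so
    that every pipeline stage is testable without human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
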