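Package: wmv1
Title: Working-Memory Content Coding Analyses for V1 Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spike-train analyses for probing visual working-memory content
    coding in primary visual cortex during delayed match-to-sample tasks:
    a content-modulation index with held-out high/low condition designation
    and cross-validation, cross-temporal population decoding with a Poisson
    independent decoder and permutation nulls, jitter-corrected
    cross-correlogram functional connectivity with a 7-SD significance rule,
    association-learning stage analyses, and a synthetic session generator
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
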