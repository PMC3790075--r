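Package: hppsim
Title: Simulating the Headturn Preference Procedure with Episodic
    Acoustic Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end computational model of the infant Headturn
    Preference Procedure (HPP). Synthetic speech stimuli (isolated word
    tokens, carrier sentences and background utterances) are converted to
    mel-frequency cepstral features, vector-quantized against learned
    acoustic prototype codebooks, and summarized as fixed-dimension
    histograms of acoustic co-occurrences (HAC). Test sentences are matched
    against an episodic memory of background experience plus familiarized
    word tokens by non-negative matrix factorization under generalized
    Kullback-Leibler divergence; the resulting familiarity scores drive an
    exponentially decaying attention function from which listening times
    are simulated under an experimenter threshold and the two-second abort
    rule. Utilities assemble test passages, run Mann-Whitney and Welch
    t-test analyses, and sweep attention-span and threshold parameters
    into significance grids with Hinton-style plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
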