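Package: phonseq
Title: Decoding Dynamic Phoneme-Sequence Codes from Multichannel Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how overlapping phoneme-evoked responses in
    multichannel recordings (e.g. MEG) encode both the content and the order
    of speech-sound sequences. Provides lexicon-derived phonetic, boundary,
    positional and information-theoretic feature annotation (phoneme
    surprisal, cohort entropy), acoustic-confound residualisation via lagged
    temporal-receptive-field models, back-to-back ridge regression for
    covariate-controlled feature decoding, temporal-generalisation analysis
    of static versus dynamic population codes, coefficient-topography
    trajectory metrics, latency-since-onset decoding, an anagram
    sequence-reconstruction simulation, and sign-flip cluster permutation
    statistics. A synthetic-data generator with planted static or drifting
    feature codes provides a fully controlled test bed for the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
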