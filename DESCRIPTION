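Package: seegspeech
Title: Speech Decoding from Cortical and Subcortical Intracranial Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding spoken Mandarin articulatory features
    (consonant place and manner of articulation, lexical tone) from
    stereotactic EEG (sEEG) recordings that sample both cortical and
    subcortical structures. Implements the full analysis chain: band-power
    feature extraction (1-30 Hz, 30-70 Hz and 70-150 Hz Hilbert-envelope
    high gamma at 200 Hz with running z-scoring), the Mandarin
    place-voice-manner consonant chart and tone labeling, a stacked
    bidirectional LSTM sequence decoder trained with Adam on sliding
    200 ms windows, and single-region / cortical-subcortical pair
    evaluation with chance-level testing and improvement ratios. A
    seeded synthetic sEEG generator with region- and band-specific
    class information makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
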