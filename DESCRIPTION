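Package: neurotext
Title: Brain-to-Text Speech Neuroprosthesis Simulation and Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-day intracortical recordings of attempted speech
    (phoneme-tuned channel rates in 80 ms bins, with day-to-day drift) and
    decodes them back to text: a frame-level phoneme classifier, a
    lexicon-constrained beam search with n-gram language models and n-best
    rescoring, neural speech-onset detection for self-paced conversation,
    decoder recalibration against nonstationarity, and the evaluation
    machinery (phoneme/word error rates via edit-distance alignment and
    percentile-bootstrap confidence intervals) used to measure it all.
    Includes readers and writers for CMUdict-dialect pronunciation lexicons
    and ARPA-format language models, plus end-to-end study harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
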