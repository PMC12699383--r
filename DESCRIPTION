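Package: lexiscreen
Title: Multimodal Early Dyslexia Screening from Gaze, Speech, Handwriting
    and Behavioural Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline, scriptable toolkit for early dyslexia screening.
    Extracts trial-level oculomotor features (fixation count, mean fixation
    duration, regression ratio, total reading time) from fixation event
    tables and classifies them with a small multilayer perceptron; scores
    oral-reading fluency from word timings and transcripts (word error rate,
    pause statistics, words per minute) with a three-criterion rule;
    analyses transcribed handwriting against an expected sentence via
    sequence alignment (character and word error rates, letter-reversal
    counts, banded risk scores); bands a nine-item behavioural
    questionnaire; fuses per-modality outputs into a combined score with
    JSON and HTML reports; and provides a syllable-level reading-support
    transformer. Includes seeded synthetic generators for every input
    stream so the full pipeline is testable without cameras, microphones,
    or external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
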