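Package: melodicdrift
Title: Time-Course Analysis of Melodic Transitional Probabilities in an
    Ordered Corpus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Corpus analysis of how the statistical structure of melody
    changes across an ordered body of works. Extracts highest-pitch melodic
    lines from MusicXML scores, encodes transitions as transposition-
    invariant interval patterns, estimates first- to seventh-order Markov
    transitional probabilities per movement and pooled per piece, filters
    the interval patterns universal to every piece of the corpus, and fits
    stepwise multiple regressions of piece order on transitional
    probabilities with variance-inflation-factor and condition-index
    collinearity screening. Ships the piece-by-pattern probability matrices
    for Beethoven's 32 piano sonatas and a synthetic corpus generator with
    controlled linear drift for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
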