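Package: crossaffect
Title: Cross-Domain Acoustic Analysis of Arousal and Valence in Speech,
    Music, and Sound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the two main dimensions of affect,
    arousal and valence, are encoded acoustically across speech, music,
    and environmental sound.  Implements frame-based extraction of 64
    suprasegmental low-level descriptors (auditory spectrum, loudness,
    MFCC, spectral shape, pitch via subharmonic summation, voice
    quality), a bank of statistical functionals producing a fixed
    6373-dimensional feature vector per clip, fusion of multi-rater
    annotations into an evaluator-weighted-estimator gold standard,
    feature relevance ranking by single-domain correlation and by the
    cross-domain correlation coefficient (CDCC), and linear
    support-vector regression evaluated within and across domains.
    Includes generators for synthetic multi-domain corpora with
    controlled acoustic drivers and simulated raters, so the complete
    pipeline can be exercised and validated without access to
    restricted corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
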