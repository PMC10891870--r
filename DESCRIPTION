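Package: pigvoc
Title: Pig Vocalization Recognition with Hybrid DNN-HMM Acoustic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A bioacoustics toolkit for classifying livestock vocalizations,
    built around a five-class pig call recognizer. Provides Kalman-filter
    speech enhancement driven by frame-wise autoregressive state-space
    models, voice-activity endpoint detection combining empirical mode
    decomposition, the Teager energy operator and short-time cepstral
    distance, 39-dimensional MFCC front-end features with delta and
    context splicing, per-class left-to-right GMM-HMM acoustic models
    trained by Baum-Welch EM, Viterbi forced alignment, a feed-forward
    network over class-state units, and hybrid DNN-HMM decoding via
    prior-scaled pseudo-likelihoods. Includes a seeded synthetic
    vocalization generator with known ground truth so the entire pipeline
    can be exercised without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
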