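Package: epgkit
Title: Machine-Learning Annotation of Electrical Penetration Graph Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for automatic annotation of electrical penetration graph
    (EPG) recordings of aphid feeding behaviour. Implements the full
    sliding-window pipeline: reading and writing Stylet+-style ASCII signal
    and annotation files, a synthetic recording generator driven by a
    behavioural grammar over the seven canonical waveforms (NP, C, pd, E1,
    E2, F, G), min-max normalisation, fixed-length segmentation with
    midpoint padding and potential-drop oversampling, handcrafted
    statistical and complexity features on raw, Fourier and symlet-4
    wavelet representations, spectrogram, Morlet scalogram and Gramian
    angular summation field images, six classifier families (1-D CNN,
    residual CNN, 2-D CNN, gradient-boosted trees, random forest,
    multinomial logistic regression), label aggregation into whole-recording
    annotations, and a two-task evaluation suite (segment classification
    metrics and whole-recording overlap rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    xgboost,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
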