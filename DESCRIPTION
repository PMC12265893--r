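Package: hicspot
Title: Spatiotemporal Anomaly Detection in Time-Series Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection of anomalous chromatin structure in
    spatiotemporal Hi-C data. A convolutional LSTM autoencoder learns the
    normal spatial organization and temporal evolution of balanced contact
    maps; frames or pixels whose reconstruction error is elevated are flagged
    as anomalous. Includes a power-law structural-perturbation simulator
    (de novo TAD formation, TAD splitting, shifting and strength changes,
    chromatin-loop strength changes) that produces ground-truthed synthetic
    contact-map series for training and validation, window extraction with
    clip plus min-max normalization, a ten-metric reconstruction-fidelity
    panel, and time-swap and scenario evaluation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
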