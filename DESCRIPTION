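Package: seqmem
Title: Decoding Sequence Memory from Hippocampal Ensemble Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal CA1 ensemble recordings from
    nonspatial odor-sequence memory tasks. Provides a session data model
    (spike trains, local field potentials, trial tables), a fully
    parameterized synthetic-session generator with recorded ground truth,
    peri-stimulus time histogram construction and trial-wise correlation
    analysis, memoryless Bayesian reconstruction of elapsed time from
    ensemble spiking with permutation chance levels and lag generalization,
    an autoencoder latent embedding of windowed ensemble activity with k-NN
    separability and Mahalanobis lag analysis, a tetrode-wise convolutional
    network for odor decoding with multinomial confidence intervals, theta
    phase extraction and cycle-resolved LASSO decoding of past, present and
    future stimuli including phase-precession statistics, and sharp-wave
    ripple detection with trial-exclusion controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
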