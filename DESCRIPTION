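Package: spectracnn
Title: 1D Convolutional Neural Networks for Mass-Spectrum Classification
    with Transfer and Cumulative Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification of profile-mode 1D mass spectra (MALDI, SELDI,
    WALDI/SpiderMass and similar ionisation technologies) with small training
    sets. Provides fixed-width m/z binning and unit-interval scaling of raw
    spectra, three 1D convolutional network architectures trained end-to-end
    on binned intensities, transfer learning by freezing the convolutional
    representation, and cumulative learning that fine-tunes one representation
    through a sequence of classification tasks before freezing it for a final
    small target task. A conventional track (log transform, SNIP baseline
    subtraction, TIC normalisation, per-class cubic-warp peak alignment and
    MAD-thresholded peak detection feeding SVM, random-forest and PCA-LDA
    baselines) is included for comparison, together with a synthetic-spectrum
    generator that emulates peak-position jitter, intensity fluctuation,
    baseline drift and class imbalance for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
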