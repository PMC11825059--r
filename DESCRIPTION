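Package: SupConTSC
Title: Instance- and Cluster-Level Supervised Contrastive Learning for
    Multivariate Time Series Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Supervised contrastive representation learning for multivariate
    time series classification (SupCon-TSC). A Siamese 1D residual
    convolutional encoder is pre-trained with a temperature-scaled supervised
    contrastive objective applied at two levels: between augmented instance
    views within a batch, and between instances and per-class cluster centers
    accumulated across batches in a FIFO memory bank. Weak and strong jittering
    augmentations feed the target and source branches. A multilayer perceptron
    classifier is then trained on the frozen pooled representation with
    cross-entropy. The package includes a reader for sktime/UEA ".ts" archives
    with padding and masking of ragged series, a synthetic generator of
    class-structured multichannel signals, Grad-CAM time-step attribution, and
    classifier-comparison statistics (pairwise win/tie counts, tie-corrected
    Friedman test, pairwise Wilcoxon signed-rank with Holm correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, cluster, foreign, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
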