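Package: fedceph
Title: Federated Learning for Orthodontic Skeletal Classification from
    Lateral Cephalograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ANB-angle-based skeletal classification of lateral
    cephalogram images and for studying federated learning across imaging
    sites. Provides landmark-file parsing and configurable threshold
    standards (Steiner, Kim) for automatic Class I/II/III labeling; a
    DenseNet-style convolutional classifier with channel-attention,
    spatial-attention, squeeze-and-excitation and spatial-pyramid-pooling
    heads, implemented with reference numerics; a FedAvg client-server
    simulation with fault-tolerant weighted aggregation; an experiment
    harness comparing local, centralized and federated training with
    weighted multiclass metrics, Cohen's kappa, one-vs-rest AUC, stratified
    k-fold splits and paired statistics; and a synthetic cephalogram
    generator emulating a two-clinic scenario with differing class ratios
    and labeling standards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
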