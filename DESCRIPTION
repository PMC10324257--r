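Package: ocusiam
Title: Siamese Attention Metric Learning for Ocular Ultrasound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for two-class classification of ocular
    B-scan ultrasound images (vitreous opacity versus posterior vitreous
    detachment) by metric learning. A siamese convolutional branch network
    with a sequential channel-plus-spatial attention block embeds images
    into a feature space, a contrastive loss trained on labelled image
    pairs shapes that space, and a k-nearest-neighbour vote over a gallery
    of training embeddings classifies queries. Includes image
    preprocessing (crop, resize, per-channel normalization), manifest and
    stratified-split management, traditional augmentation, a synthetic
    fundus-ultrasound image generator for fully reproducible end-to-end
    testing, evaluation metrics, and experiment harnesses for attention
    ablations, neighbourhood-size sweeps and classifier comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    randomForest,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
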