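Package: faunadetect
Title: Weakly Supervised Detection of Megabenthic Fauna in Seafloor Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated generation of bounding-box annotations for
    megabenthic fauna in seafloor photographs, and downstream detection
    evaluation and ecological summarisation. Images are over-segmented into
    superpixels with graph-based segmentation, unsupervised features are
    learned with a small variational autoencoder, anomalous superpixels are
    scored with a from-scratch isolation forest and filtered into weak
    annotations by percentile thresholding or a trainable binary patch
    classifier. Includes COCO-style average precision and recall, greedy
    non-maximum suppression, confusion matrices, a configurable noisy oracle
    detector, abundance (individuals per square metre), exponential Shannon
    diversity and gridded spatial density, plus a seeded synthetic
    benthic-survey generator for end-to-end exercise of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
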