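Package: annotransfer
Title: Semi-Automated Transfer of Tumor Annotations from H&E to
    Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for carrying pathologist tumor annotations from
    hematoxylin-and-eosin (H&E) histology exports onto fluorescence
    whole-sample images such as those produced by microscopy with
    ultraviolet surface excitation (MUSE). Implements landmark-based
    second-order polynomial registration fitted from manually paired
    control points, annotation recovery by image subtraction with
    morphological closing and filling, Canny-based tissue masking,
    refinement of the annotation against the tissue mask, inverse
    transfer of the refined annotation into raw fluorescence pixel
    space, and three agreement metrics (Dice coefficient, normalized
    symmetric Hausdorff distance, and feature-space cosine similarity)
    with boxplot-style batch summaries. A synthetic phantom generator
    with known ground-truth warps, masks and landmarks makes every
    stage testable without slide data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
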