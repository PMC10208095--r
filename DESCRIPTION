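Package: segqc
Title: Reference-Free Quality Assessment of Cell Segmentation in
    Multichannel Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates cell segmentation of multichannel fluorescence
    tissue images without a reference segmentation. Matches and repairs
    cell and nuclear label masks, computes a panel of fourteen
    segmentation-quality metrics covering mask coverage and the
    homogeneity of segmented cells, and combines them into an overall
    quality score through a principal-component model. Also provides
    symmetric benchmarks against a second segmentation (F1 at a Jaccard
    threshold, threshold-averaged F1, and a symmetrised SEG score),
    controlled degradation simulators (additive Gaussian noise,
    downsampling, undersegmentation by merging contacting cells, mask
    shifting), a Voronoi baseline segmenter, and a synthetic-tissue
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    cluster,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
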