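Package: micropost
Title: Microtissue Contractility Quantification on Cantilever Post Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-based quantification of engineered microtissue
    contractility on paired elastomer cantilever posts, and plate-level
    compound screening analytics. Provides a ground-truthed synthetic image
    generator for wells and whole screening plates; an image-conditioning
    chain (retrospective flat-field shading correction, tile stitching with
    integer-shift refinement, maximum-intensity projection, mean binning);
    random-forest pixel classification with rule-based segmentation QC;
    Euclidean distance-transform metrology of inter-post tip distance,
    percent contraction, cantilever force, tissue area and viability;
    closed-form Euler-Bernoulli cantilever mechanics and tensile-curve
    analysis; and robust median-absolute-deviation hit calling for 96-well
    screens with damage and death exclusions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
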