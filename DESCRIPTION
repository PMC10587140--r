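Package: ddcquant
Title: Quantification of Dilated Deep Capillaries on En Face OCTA Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies dilated deep capillaries (DDC) on en face optical
    coherence tomography angiography (OCTA) images of the deep retinal
    layers. The pipeline binarizes an angiogram with ImageJ-style automatic
    contrast adjustment followed by Kapur maximum-entropy thresholding,
    removes normal-caliber capillaries with iterative neighbor-count binary
    erosion, builds axial-length-corrected (Bennett) ETDRS sector masks
    (central 1 mm subfield plus four parafoveal quadrants out to 2.5 mm),
    and reports the per-sector DDC index as a relative-area percentage.
    Includes a seeded synthetic vessel-phantom generator with ground-truth
    masks, per-eye eligibility checks, batch processing, and the
    accompanying statistical battery (median/IQR summaries, Kruskal-Wallis
    with Bonferroni correction, Fisher's exact test, ROC AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
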