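Package: fibroCPA
Title: Automated Collagen Proportionate Area Quantification on Picrosirius
    Red Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automated quantification of liver fibrosis on picrosirius
    red (PSR) stained whole-slide images. Tissue is delineated from optical
    density, stain axes are estimated by singular value decomposition of the
    tissue OD cloud, pixels are projected on the third singular vector and
    thresholded to segment collagen, and fibrosis is reported as the collagen
    proportionate area (CPA). Includes a synthetic PSR slide and cohort
    generator with exact ground truth, per-animal aggregation, encodings of
    the Ishak, modified Ishak and NASH CRN fibrosis staging systems, and the
    validation statistics used to benchmark CPA against hydroxyproline
    content and histological stages: Spearman correlation, Fisher z, and
    Steiger's one-sided test for comparing dependent correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
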