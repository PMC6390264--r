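Package: callusHisto
Title: Histomorphometry of Fracture-Callus Sections with Local Bone-Density Mapping
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative histomorphometry for longitudinal sections of healing
    long-bone osteotomies. Takes pre-segmented tissue-label rasters, constructs
    the callus region of interest around the osteotomy gap, partitions it into
    anterior and posterior halves, and measures callus, new-bone and cartilage
    areas and area fractions (Cl.Ar, nB.Ar, Cg.Ar, nBV/TV, CgV/TV). Implements
    a per-pixel local new-bone density map (nB.Dn): the bone area fraction
    within a fixed-radius disk around each callus pixel, segmented into low,
    medium and high density classes. Includes a synthetic-section and
    synthetic-study generator with known ground truth, linear mixed models with
    a random intercept per animal for group-level inference, and an end-to-end
    pipeline writing report tables and false-colour overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
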