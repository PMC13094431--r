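Package: lipidmsi
Title: Spatial Lipidomics Pipeline for DESI Mass Spectrometry Imaging with
    Cross-Modal MS2 Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for spatial lipidomics by
    desorption electrospray ionization mass spectrometry imaging (DESI-MSI):
    reading and writing continuous-mode imzML pixel grids, TIC normalization,
    baseline correction, peak picking, cross-replicate alignment and
    deisotoping, unsupervised tissue segmentation by bisecting k-means under
    a correlation distance, two-tier selection of adipose-enriched lipid
    features (FDR-filtered Welch tests followed by replicate-level ROC AUC
    thresholding), adduct-aware accurate-mass lipid annotation against a
    combinatorial lipid database, and cross-modal Level-2 identification
    against LESA-MS2 spectra via class-diagnostic fragment rules. Includes a
    synthetic phantom generator that emulates multi-tissue full-body
    sections with planted adipose enrichment and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    png,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
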