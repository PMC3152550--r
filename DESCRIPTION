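Package: dropscreen
Title: High-Content Screening Pipeline for Cellular Lipid-Droplet Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for image-based high-content
    screens of lipid-droplet (LD) formation. Generates synthetic two-channel
    (nuclei / neutral-lipid) fluorescence fields with per-cell ground truth,
    segments nuclei, delineates cytoplasmic territories, detects and assigns
    LD spots to cells, and summarises wells into mean-LDs-per-cell,
    nuclei-per-field and LD-count distributions. Plate-level analytics cover
    duplicate averaging, normal-range (mean +/- k*SD) hit calling for LD
    modulators and cytotoxic treatments, hit-rate arithmetic, percent
    inhibition, fold change, dose-response summaries with optional sigmoid
    fits, single-exponential uptake-kinetics fitting, and Z-prime assay
    quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
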