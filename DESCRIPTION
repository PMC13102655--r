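Package: aerateCT
Title: Hounsfield-Unit Aeration Profiling of Micro-CT Lung Volumes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative densitometry of small-animal thorax micro-CT scans.
    Segments lung parenchyma by Hounsfield-Unit (HU) thresholding with
    connected-component and morphological cleanup, computes the conventional
    two-compartment (well-/poorly-aerated, split at -500 HU) and a refined
    ten-bin (80 HU per bin over -900 to -100 HU) aeration-density profile as
    per-bin volumes and percentages of total lung volume, and compares
    treatment groups with Welch/Student t-tests and per-time-point two-way
    ANOVA (treatment x HU bin) followed by Monte-Carlo Dunnett many-to-one
    adjustment. Includes a synthetic thorax-phantom generator with analytic
    ground truth for validating the pipeline and for power experiments
    contrasting the sensitivity of the two binning schemes to early
    parenchymal densification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    tools,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    readr
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    mvtnorm,
    withr
Config/testthat/edition: 3
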