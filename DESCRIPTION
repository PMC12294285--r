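Package: cobraline
Title: COBRA LINE-1 Methylation Patterns and Calibrated Case-Control Simulation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the Combined Bisulfite Restriction Analysis (COBRA) assay of
    the LINE-1 retroelement promoter: an in-silico bisulfite-conversion and
    restriction-digest engine for the two interrogated CpG sites (TaqI and
    MluCI), the gel-densitometry deconvolution that converts band intensities
    at 160/98/80/62 bp into total methylation (mC) and the four two-CpG
    methylation patterns (mCmC, uCmC, mCuC, uCuC), a forward densitometry
    simulator, a Gaussian-copula cohort generator calibrated to published
    type 1 diabetes case-control summary statistics, and the nonparametric
    statistical battery (Mann-Whitney, chi-squared, Spearman, power by
    simulation) that rebuilds the study's result tables from simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Biostrings,
    Matrix,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
biocViews: Epigenetics, DNAMethylation, Software, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
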