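Package: cnsurv
Title: Copy-Number Landscape Analysis with Survival Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing tumour DNA copy-number profiles in
    clinical-trial cohorts: probe-level log2-ratio preprocessing
    (dewaving, median and post-segmentation mode normalisation,
    tumour-purity correction), circular binary segmentation, four-state
    aberration calling with a Gaussian mixture, reduction of the call
    matrix to chromosomal subregions, permutation log-rank association
    of region status with progression-free survival per treatment arm
    with permutation-based false discovery rates, dosage-sensitivity
    filtering of genes against paired copy-number/expression data,
    amplification cataloguing, and cell-line drug-sensitivity (IC50)
    validation of candidate regions. Includes a synthetic-data
    generator that emulates the statistical structure of such cohorts
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
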