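Package: fluoroquant
Title: Quantification of Pseudo-Colored Fluorescence in Surgical Specimen Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-hoc quantification of indocyanine-green (ICG)
    fluorescence in pseudo-colored still images of surgical specimens, as
    produced by near-infrared exoscopes that render detected fluorescence as
    blue on an otherwise white-background photograph. Provides hue/intensity
    color thresholding on the 0-255 HSI scale, surface-fluorescence percentage
    and background-subtracted average fluorescence intensity measurements, the
    ordinal 0-4+ semi-quantitative surface score, and the agreement (percent
    agreement, simple and weighted Cohen's kappa), rank-based comparison
    (Wilcoxon-Mann-Whitney, Friedman), logistic-regression/ROC cut-point and
    Spearman association statistics used to validate such scoring systems.
    Includes a synthetic lymph-node image generator with exact pixel-level
    ground truth so the whole pipeline is testable without clinical data, and
    a batch command-line workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    pracma,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    e1071,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
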