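Package: nucleograde
Title: Nucleolar Prominence Morphometrics and Survival Stratification for
    Clear Cell Renal Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale quantitative-histology pipeline for clear cell
    renal cell carcinoma (ccRCC). Generates seeded synthetic H&E-like
    tiles with ground-truth nuclei and synthetic survival cohorts;
    segments nuclei as star-convex polygons (probability and radial
    distance maps, polygon candidates, IoU non-maximum suppression);
    grades cells by nucleolar prominence with a deterministic rule set;
    profiles regions of interest (G3-cell density per square millimetre
    and percentage); selects grade-discriminating thresholds by ROC and
    Youden's J with one-way ANOVA and Tukey comparisons; and stratifies
    cohorts into four prognostic tissue-pattern quadrants evaluated with
    Kaplan-Meier curves, the log-rank (Mantel-Cox) test and Fisher's
    exact test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
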