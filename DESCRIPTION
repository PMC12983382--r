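Package: bgrisk
Title: Modified Brandwein-Gensler Histological Risk Scoring for Oral
    Squamous Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a modified Brandwein-Gensler histological risk
    assessment pipeline for oral squamous cell carcinoma. Quantifies
    tumor-infiltrating lymphocytes as the percentage of stromal area
    occupied by mononuclear inflammatory cells from annotated field
    masks, dichotomizes cases at the cohort median, combines worst
    pattern of invasion grade 5, perineural invasion and low TIL
    density into an additive three-component risk score, and provides
    the association and survival statistics used to evaluate the
    score: Pearson chi-square and linear-by-linear trend tests for
    cross-tabulations, one-way ANOVA from raw data or from printed
    group summaries, Pearson correlation, rank-based ROC analysis,
    Kaplan-Meier estimation with restricted mean survival, and
    log-rank tests. A synthetic-cohort generator with the statistical
    structure of a 58-patient OSCC cohort makes every stage testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    png
Suggests:
    tiff,
    withr,
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
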