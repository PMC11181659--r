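Package: armSL
Title: Chromosome-Arm Synthetic Lethality Discovery from CRISPR Dependency
    Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate synthetic-lethal partners of recurrent
    chromosome-arm deletions in cancer cell line panels. Classifies cell
    lines as arm-deleted or not from gene-level relative copy number,
    scores differential gene dependency (dCERES) between the groups with
    per-gene Wilcoxon rank-sum tests and covariate-weighted false
    discovery rate control, and ranks expression-buffering (paralog
    synthetic-lethal) gene pairs by a balanced, competition-weighted
    Pearson correlation. Also provides the accompanying label-free
    proteomics differential-abundance workflow (valid-value filtering,
    quantile normalization, downshifted imputation, moderated t-tests)
    and a synthetic DepMap-like cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
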