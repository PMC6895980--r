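Package: methexpr
Title: Integration of DNA Methylation and Gene Expression in Tumor-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates genome-wide CpG methylation (450K-style beta values)
    with gene-level RNA read counts in a tumor versus normal design, as used
    for gonadotroph nonfunctioning pituitary adenomas: differentially
    methylated position (DMP) calling by delta-beta and FDR thresholds,
    negative-binomial differential expression with fold-change thresholds,
    per-CpG Spearman methylation-expression correlation across tumor samples,
    stratification by gene region (promoter/body) and CpG context
    (island/shelf-shore/open sea), concordance quadrant classification of
    DMP-DEG pairs, and local hypergeometric over-representation analysis.
    Ships a synthetic-data generator with planted ground truth so every stage
    is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
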