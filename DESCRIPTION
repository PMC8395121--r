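Package: degconcord
Title: Cross-Platform Differential Expression Concordance and Transient
    Time-Course Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing differential gene expression results across
    measurement platforms (microarray versus RNA-Seq) and across time points.
    Provides per-gene regulation calls, directional overlap accounting,
    set-inclusion sweeps over progressively stricter significance cutoffs,
    Spearman fold-change concordance, consensus DEG sets, gene biotype
    composition, per-chromosome enrichment via dual Fisher exact test
    families, three-time-point trajectory classification with adaptation
    fractions, pre-ranked gene set enrichment with a gene-permutation null,
    and self-contained statistical primitives (Benjamini-Hochberg adjustment,
    two-sided Fisher exact test, quantile normalization, median polish).
    A seeded synthetic generator produces paired-platform, multi-time-point
    differential expression tables with planted ground truth so every
    analysis stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea
Config/testthat/edition: 3
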