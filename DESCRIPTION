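Package: safeguardR
Title: Safeguard Repressor Screening from Expression Specificity and Promoter Motif Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate safeguard repressors: cell-type-specific,
    lifelong-expressed transcription factors whose DNA-binding motifs are
    depleted at their own cell type's signature-gene promoters. Implements
    median-CPM normalization, one-vs-rest signature derivation with overlap
    removal, promoter motif-density scoring, combined Z-based safeguard
    scores with lifelong-expression filters, regulon construction from
    binding peaks and differential expression, per-cell module and activity
    scores with a rank-proportion transduction filter, hypergeometric and
    Fisher gene-set statistics, and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
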