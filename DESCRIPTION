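Package: ParaffinPolish
Title: Combinatorial and Classifier-Based Refinement of Somatic SNV Calls
    from FFPE Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to improve somatic single-nucleotide-variant (SNV) call
    sets derived from formalin-fixed paraffin-embedded (FFPE) tumour
    genomes.  Variant call sets from several callers are partitioned into
    the seven disjoint regions of a three-caller Venn diagram and all 127
    region-subset call sets are scored with estimated recall, precision and
    F1 against a composite fresh-frozen (FF) ground truth (the intersection
    and union of two FF callers).  A logistic-regression classifier over 31
    pileup-derived read features filters FFPE-specific artifact calls
    (deamination-driven C>T/G>A false positives) from any single caller's
    VCF.  A seeded simulator generates synthetic references, tumour BAMs
    with planted variants and FFPE-like artifacts, and caller VCFs, so the
    whole workflow is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    glmnet,
    BiocGenerics,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
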