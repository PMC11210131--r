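Package: clonalCRE
Title: Clonality and Penetrance Analysis of Cis-Regulatory Elements in
    Disease-Stage ATAC-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dissects chromatin-accessibility heterogeneity across disease
    stages in a patient cohort profiled by ATAC-seq. Builds a cohort-wide
    master list of accessible cis-regulatory elements (CREs), scores each
    element with a per-sample Clonality Index (percentile rank of
    depth- and size-normalized enrichment) and a cohort Penetrance Index
    (number of samples sharing the element), tests differential
    accessibility with a cohort-resampling null, selects and clusters
    dynamic CREs on z-scaled log2 TMM-normalized accessibility, quantifies
    enhancer RNA over the non-exonic portion of CREs, classifies
    promoter-capture Hi-C loops and assigns enhancer-gene targets, and
    ranks genes from CRISPR dependency screens by lineage-restricted
    essentiality. A synthetic-cohort generator with a negative-binomial
    count model makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
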