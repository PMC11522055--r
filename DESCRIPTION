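Package: triomix
Title: Integrative Analysis of DNA Methylation, mRNA and miRNA Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking reduced-representation bisulfite sequencing (RRBS)
    DNA methylation with mRNA and miRNA expression across tissues. Provides
    per-CpG differential methylation calling (Fisher exact or binomial
    likelihood-ratio tests with Benjamini-Hochberg adjustment), negative-binomial
    differential expression with median-of-ratios normalisation, strand-aware
    promoter (TSS1500 + 5'UTR) and gene-body annotation of CpG sites,
    expression-tier-stratified Spearman summaries of methylation-expression
    coupling, seed-match miRNA target prediction with negative-correlation
    filtering, and construction of methylation -> miRNA -> mRNA regulatory
    chains. A coupled tri-omics simulator with planted truth supports
    calibration and recovery benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
biocViews: DNAMethylation, DifferentialExpression, Epigenetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
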