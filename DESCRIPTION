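Package: lncmeth
Title: Crosstalk Inference Between DNA Methylation and lncRNA Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates paired tumor/paratumor Illumina 450K methylation
    profiles with long noncoding RNA (lncRNA) differential-expression
    tables to infer crosstalk between DNA methylation and lncRNA
    regulation. Provides paired differential-methylation calling with
    Benjamini-Hochberg correction, genomic annotation of significant CpG
    sites against SNP, CpG island/shore, enhancer and DNase
    hypersensitive site tracks, coordinate-based integration of
    methylation and lncRNA signals over promoters (TSS +/- 1 kb) and gene
    bodies, target-gene set intersection with hypergeometric enrichment,
    and z-score-stratified Kaplan-Meier / log-rank survival association.
    A synthetic-data generator with planted effects makes the whole
    pipeline testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
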