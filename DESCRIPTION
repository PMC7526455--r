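Package: funsnp
Title: Prioritization of Functional Noncoding GWAS Variants and Their
    Regulatory Target Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative prioritization of functional noncoding GWAS
    variants for complex (auto)immune diseases and prediction of their
    regulatory target genes. Implements linkage-disequilibrium expansion
    of tag SNPs into positive/background/negative variant classes,
    fold-enrichment-weighted epigenetic functional scoring against an
    empirical negative-SNP null, allele-specific transcription-factor
    motif calling with exact position-weight-matrix p-values, molecular
    QTL evidence filtering, multi-evidence target-gene prediction
    combining cis-QTL support, 3D chromatin-interaction support and
    Bayesian colocalization (approximate Bayes factors and PICS-based
    credible sets), regulatory transcription-factor network assignment,
    and rule-based drug-target prediction over protein-protein
    interaction networks. Ships a deterministic synthetic-fixture
    generator with a planted-truth manifest so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
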