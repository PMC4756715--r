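Package: aneuscan
Title: Structural Variant and Copy-Number Instability Analysis for Aneuploid Clonal Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of the computational chain used to
    quantify genomic instability caused by extra chromosomes: detection and
    clustering of discordant mate pairs with orientation-based rearrangement
    typing, nucleotide-resolution breakpoint-junction microhomology analysis,
    probe-threshold copy-number aberration calling, cross-clone unique-CNA
    filtering by reciprocal overlap, a case/control label-permutation
    enrichment test with an exact closed-form companion, and fragile-site
    breakpoint annotation. A synthetic-data module generates toy genomes,
    rearranged derivatives with engineered junction microhomology, mapped
    mate-pair records, clonal CNA call tables and probe profiles with full
    ground truth, so every step of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
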