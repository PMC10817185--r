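Package: karyoscope
Title: Nigon-Element Chromosome Painting and Sex Chromosome Inference for
    Nematode Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying chromosome evolution in nematode genomes:
    painting chromosomes by ancestral linkage (Nigon) elements using
    conserved single-copy orthologs, identifying sex chromosomes from
    sexed read-depth tracks normalised by the autosomal median, calling
    the X-Y shared (male-diploid) regions that mark young neo-Y
    chromosomes, summarising X-Y divergence as windowed heterozygous SNP
    density, and computing sequence-feature tracks (telomere repeat
    arrays, softmask repeat density, assembly metrics). A seeded
    synthetic-data generator emulates fused karyotypes, ploidy-aware
    sexed coverage with embryo-driven dilution of female X coverage, and
    gametolog SNP signals, so every pipeline stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    GenomicRanges
Imports:
    methods,
    tools,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    BiocGenerics,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
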