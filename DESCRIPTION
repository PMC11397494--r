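Package: CNEaccel
Title: Conserved Noncoding Elements and Lineage-Specific Accelerated
    Evolution in Nematode Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide detection of conserved noncoding elements (CNEs)
    from reference-anchored multiple alignments with a two-state
    phylogenetic hidden Markov model, and branch-targeted likelihood-ratio
    tests for lineage-specific accelerated evolution of those elements,
    modelled on the phastCons/phyloP workflow used to study the convergent
    evolution of hermaphroditism in Caenorhabditis. Includes downstream
    element-level statistics (nucleotide diversity from population
    variants, annotation-overlap enrichment, nearest-gene assignment), a
    cross-species sex-biased-expression transition analysis, and seeded
    synthetic-data generators that emulate every input so each stage is
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    phangorn
biocViews: Genetics, Phylogenetics, ComparativeGenomics, HiddenMarkovModel,
    Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
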