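Package: graphsv
Title: Breakpoint-Graph Genotyping of Structural Variants from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotypes structural variants (deletions, insertions, duplications,
    inversions and breakends of 50 bp or more) in short-read sequencing data by
    local realignment to breakpoint-aware pangenome graphs. Each variant is
    encoded by one or two bounded breakpoint sequences inserted alongside the
    reference in an acyclic graph; reads extracted from a window (including
    clipped reads and unmapped reads with a mapped mate) are realigned to the
    local haplotype contexts and genotype likelihoods are computed from per-read
    allele support. Deletions and duplications are additionally genotyped from
    the change in alignment coverage, and the aggregated call takes the model
    with the higher genotyping quality. Also provides position/size-threshold
    merging of structural-variant sites discovered across many samples,
    benchmark evaluation (breakpoint-precision recall and false discovery rate,
    size-binned recall, call-set concordance), pedigree statistics (Mendelian
    inheritance errors, parent-to-offspring transmission rates, carrier
    spectra), and a deterministic diploid pedigree simulator that plants
    structural variants with known genotypes and generates paired short reads
    with linear-reference placements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    igraph,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
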