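Package: guideBalancer
Title: Selection of Single Guide RNAs for Balancer Chromosome Engineering
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies Streptococcus pyogenes Cas9 single guide RNAs (sgRNAs)
    that cut one chromosome at multiple, well-spaced sites while minimizing
    off-target cutting elsewhere in the genome, for seeding the inversions of
    engineered balancer chromosomes. Scans both strands of each chromosome for
    NGG protospacer-adjacent-motif sites, bins sites by their 18-bp
    PAM-proximal seed, rejects seeds recurring on other chromosomes, models
    recombination suppression as a +/- 2 Mbp protection window around each
    predicted cut, scores off-target sites with a multiplicative
    cutting-frequency-determination (CFD) penalty model, and ranks candidate
    guides by the sgRNA Sequence Value (SSV), the ratio of chromosome coverage
    to one plus the summed off-target CFD burden. Includes a synthetic-genome
    fixture generator with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CRISPR, SequenceMatching, Coverage, GenomeAnnotation, Software
RoxygenNote: 7.3.3
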