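Package: exonEvo
Title: Tracing Exon-Intron Structural Changes in Gene Subfamilies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exon-boundary-aware comparative analysis of gene structure
    evolution. Builds codon-projected multiple alignments with exon
    boundaries mapped into alignment coordinates, classifies structural
    change events between homologous genes (exonization and
    pseudoexonization, exon and intron gain or loss, intraexonic
    insertions and deletions, stop-codon-driven terminal changes), places
    events on a rooted phylogeny by maximum parsimony with Dollo-style
    tie-breaking, and reconstructs ancestral exon-intron structures at
    internal nodes. Includes a gene-family simulator with a fully recorded
    event history and deterministic fixtures replaying classic MADS-box
    structural-change scenarios, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
biocViews: Alignment, Phylogenetics, ComparativeGenomics, GenePrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'align.R'
    'codon-align.R'
    'events.R'
    'gene-models.R'
    'filter.R'
    'parsimony.R'
    'simulate.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
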