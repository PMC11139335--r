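Package: introtrace
Title: Phylogenetic Profiling of Gene Families from Intron Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of gene families whose
    protein sequences carry little phylogenetic signal by using the positions
    and phases of spliceosomal introns as near-irreversible characters.
    Parses genomes (FASTA) and annotations (GFF3) into coding-coordinate
    intron annotations, projects intron positions through protein multiple
    alignments to define shared-position ortholog classes, reconstructs each
    character's single origin and independent losses on a species tree by
    Dollo parsimony, scores intron insertion points against the protosplice
    consensus (AG|GT), detects concerted evolution between paralogs via
    per-exon gene-tree monophyly, and tests whether inferred gene losses
    track genome-assembly quality. A seeded gene-family simulator emits
    FASTA/GFF3/Newick/truth bundles so the whole workflow is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
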