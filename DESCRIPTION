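Package: indelmine
Title: InDel Marker Discovery and Gel-Based Genotyping from Assembled Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Develops insertion/deletion (InDel) markers resolvable on agarose
    gels from per-genotype assembled contigs. Contigs from genotypes of the
    same market class are aligned pairwise or three-way with an exact
    affine-gap local aligner; length differences between query and subject are
    extracted as InDel candidates, filtered for minimum size, screened for
    uniqueness against a reference genome, and turned into consensus regions
    from which tightly constrained primer pairs are designed (narrow melting
    temperature window, product size about ten times the InDel size). Markers
    are named by chromosome and physical position. A reference-based pileup
    scanner calls InDels from alignments with depth and variant-allele
    frequency thresholds. In-silico PCR, virtual gel scoring, multiplex
    compatibility checks, shared-allele distances, neighbor-joining trees with
    bootstrap support and Fst complete the genotyping side. A synthetic
    fixture generator with recorded ground truth makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
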