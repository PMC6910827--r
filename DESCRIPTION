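Package: chromoshatter
Title: Simulation and Forensic Analysis of Rearranged Transferred Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for chromosomal rearrangements arising on a
    transferred homolog in trisomic and tetrasomic cell lines. Simulates
    shattering-type (chromothripsis) and replicative-type (chromoanasynthesis)
    rearrangements restricted to the transferred homolog and renders SNP-array
    style BAF/LRR profiles, binned quantal copy-number segments, breakpoint
    junction contigs and read-pair allele counts with ground truth retained.
    Provides copy-number calling with aneuploid correction, consecutive-segment
    merging, reciprocal-overlap uniqueness filtering, B-allele-frequency
    haplotype assignment of copy-number aberrations to the transferred versus
    endogenous homolog, breakpoint junction classification (orientation,
    microhomology, non-templated and templated insertions, copy-number
    oscillations), and chromosome-size- and ploidy-aware permutation tests for
    enrichment of de novo aberrations on the aneuploid chromosome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
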