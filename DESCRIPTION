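Package: ucekit
Title: Alignment-Free Discovery and Regulatory Analysis of Ultraconserved Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ultraconserved elements (UCEs) across a cohort of genome
    assemblies without whole-genome alignment, by extracting reference-unique
    k-mers, testing their exact presence in every query genome, fusing
    overlapping universal seeds and verifying the reconstituted elements.
    Provides the downstream analyses used to characterise such elements:
    classification against gene models, a length-matched uniquely-mapping
    random-element null, single-linkage clustering, inter-element distance
    statistics, transcription-factor and Polycomb-group peak enrichment with
    Benjamini-Hochberg correction, multifunctionality scoring of exonic
    elements, alternative-splicing and splicing-enhancer motif tests, and a
    synonymous-site census with Fisher's exact test for coding-independent
    constraint. Includes seeded simulators for genome cohorts with planted
    conserved elements, annotation and ChIP-peak tracks, and codon alignments,
    so every stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
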