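Package: rippmine
Title: Bait-Anchored Mining, Networking and Mass Annotation of RiPP Precursor Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale pipeline for discovering ribosomally synthesised and
    post-translationally modified peptide (RiPP) biosynthetic gene clusters
    anchored on a bait enzyme family such as YcaO-domain proteins. Parses
    annotated genomes from GenBank flat files, extracts flanking windows
    around bait CDS features, calls candidate short open reading frames that
    may encode precursor peptides, groups peptides into families by
    global-alignment identity networking, discovers conserved ungapped motifs
    by expectation maximisation, and converts observed LC-MS ions into
    structural hypotheses by exhaustive core-peptide and modification
    monoisotopic-mass matching. Ships a synthetic-data module that generates
    genomes with planted gene clusters, peptide families with controlled
    identities and planted motifs, and ion lists with ground-truth tables, so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    withr
Config/testthat/edition: 3
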