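Package: gapscope
Title: Assembly-Gap Forensics for Draft Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies why draft genome assemblies fragment and what their
    gaps hide. Finds N-run gaps, classifies their causes from adjacent repeat
    annotation, lifts gap flanks onto a curated reference with a built-in
    seed-and-extend local aligner, and reports what the lifted intervals
    contain. Adds dark-matter completeness metrics for avian-like genomes:
    GC-rich window census, canonical G-quadruplex motif scanning, per-class
    repeat recovery, a multicopy-exon census via six-frame translated search,
    gene presence/absence calls, and sex-linkage calling from male/female
    read-depth ratios. A seeded synthetic truth-genome generator (macro- and
    GC-rich microchromosomes, repeat-rich W, satellite arrays, LTR elements,
    truncated LINEs, tandem exon paralogs) produces fragmented drafts with
    known gap causes so the whole pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
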