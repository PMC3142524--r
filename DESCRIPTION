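Package: panann
Title: Pan-Genome Annotation Consistency from Whole-Genome Multiple Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uses a reference-independent whole-genome multiple alignment (MAF)
    of closely related prokaryotic genomes to build positional ortholog groups
    of annotated CDS features and to audit annotation quality across the
    pan-genome. Detects inconsistently placed translation initiation sites,
    inconsistent stop codons, fragmented or disrupted genes, and missing
    annotations, and proposes ranked alternative gene structures that are valid
    ORFs (bacterial translation table 11) across the aligned genomes, including
    single-frameshift repairs at alignment indels. Ships a ground-truthed
    synthetic pan-genome simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
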