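Package: numtkit
Title: Annotation of Nuclear Mitochondrial Insertions in Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and annotates nuclear mitochondrial insertions (Numts) in
    genome assemblies using circularity-aware local alignment against a doubled
    mitochondrial reference, merges high-scoring pairs into Numt loci with a
    dual-coordinate proximity rule, calls presence-absence dimorphism between
    assemblies from insertion/deletion variants, scans genotyped structural-variant
    call sets for polymorphic Numts, and tests Numt presence in outgroup
    assemblies with flank-anchored search. Includes a seeded synthetic-fixture
    generator that plants Numts with known ground truth so the whole pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    igraph,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
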