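Package: ctt
Title: Closing Target Trimming for Gene Superfamily Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers unannotated members of gene superfamilies in assembled
    genomes by the Closing Target Trimming (CTT) strategy: candidate regions
    are anchored with a translated homology search of family seed domains,
    neighbouring homologous loci are iteratively trimmed away until the
    anchor locus is exposed, the gene structure is predicted by spliced
    protein-to-genome alignment with consensus voting across reference
    templates, pseudogenes (premature stops, frameshifts, or no viable
    transcript) are classified, and new members are confirmed by a family
    domain profile scan. Includes a synthetic-genome generator with planted
    hidden loci, tandem arrays and pseudogenes, and evaluation metrics for
    hold-out rediscovery sensitivity, prediction specificity and new-finding
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    withr,
    optparse,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
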