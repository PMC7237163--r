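Package: termini
Title: Annotation-Independent Detection of RNA 3' Ends from Paired-End RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide, annotation-independent calling of transcription
    termination sites (TTS) from strand-specific paired-end RNA-seq libraries
    that preserve native RNA 3' ends. Candidate ends are scored by internal
    enrichment (end counts against the geometric mean of linked fragment-start
    counts, with empirical p-values from the reciprocal start-score background)
    and, independently, by a sliding-window z-score peak caller; sites supported
    by both lines of evidence within 10 nt become TTS calls. Downstream tools
    classify TTS (first/secondary rank, intergenic/coding, antisense), measure
    3' UTR lengths, compute nucleotide profiles around termination sites and
    export motif windows. An annotation-anchored baseline caller
    (mean-insert-length downstream regions) is included for comparison, and a
    seeded mate-pair simulator provides ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    withr,
    yaml,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
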