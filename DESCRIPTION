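Package: sangerstitch
Title: Merge Overlapping Sanger Walking Reads into a Full-Length Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stitches ordered, overlapping Sanger (primer-walking) sequencing
    reads into a single full-length sequence. Reads plain-text sequence files
    (seq, fasta, or txt), reverse-complements reverse-strand reads, globally
    aligns each adjacent pair with affine gap penalties, locates the first run
    of n consecutive matching bases to define the splice boundary, and emits
    the merged sequence together with EMBOSS needle (srspair) style alignment
    reports, forwardized intermediates, and a timestamped run log. Includes a
    synthetic walking-read simulator with ground-truth splice coordinates for
    validation, tidy accessors for fitted results, and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
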