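Package: homeoassign
Title: Subgenome-Specific Base Assignment at Homeolog-Specific
    Polymorphisms in Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns subgenome-specific base identity at
    homeolog-specific polymorphism (HSP) sites in allopolyploid
    transcriptomes with up to three subgenomes.  Read pairs aligned to a
    concatenated in silico reference are condensed into base patterns
    over HSP positions, cleaned of sequencing-error and embedded
    patterns, matched to diploid progenitor-relatives by sequence
    identity (with a provision for one distant relative), and resolved
    into per-position, per-subgenome base calls by iterative consensus.
    Includes a synthetic allopolyploid read simulator with ground truth,
    an evaluation harness, shared-base and tri-homeoallelic summary
    statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    data.table,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
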