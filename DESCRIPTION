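Package: codonuse
Title: Synonymous Codon Usage Bias Analysis for Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis of synonymous codon usage bias in protein-coding
    nucleotide sequences: open reading frame selection and translation,
    per-codon counting, relative synonymous codon usage (RSCU), Wright's
    effective number of codons (Nc) and its GC3-expected counterpart,
    nucleotide and GC3s composition, Kyte-Doolittle GRAVY hydropathy,
    and rare-codon frequency against a host codon-usage reference.
    Ships per-codon count tables and nucleotide compositions for the four
    human albumin superfamily genes (ALB, AFP, AFM, VDBP) together with a
    human codon-usage reference, plus a seeded generator of coding
    sequences with controlled codon-usage structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
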