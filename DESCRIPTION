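Package: rflpdesign
Title: Design of PCR-RFLP Genotyping Assays for SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline design of PCR-RFLP (restriction fragment length
    polymorphism) genotyping assays. Given SNP-containing template sequences
    in bracket ([A/G]) or IUPAC ambiguity notation and a restriction-enzyme
    table in a REBASE-style tab-separated dialect, the package mines enzymes
    whose digestion discriminates the alleles on either strand, simulates
    post-PCR digestion fragment patterns per genotype, and designs natural
    primer pairs as well as mutagenic (dCAPS-style) mismatch primers that
    create an allele-specific restriction site when no natural one exists.
    Primer thermodynamics (GC content, salt-adjusted melting temperature,
    Tm difference, product length), enzyme degeneracy class, suppliers and
    price are reported for every assay. Bi-, tri- and tetra-allelic SNPs and
    indels are supported, with up to 50 variants per sequence.
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
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
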