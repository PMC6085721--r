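Package: rfamine
Title: Mining RFamide Neuropeptide Precursors from Transcriptome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screen for RFamide-family neuropeptide precursor
    genes in assembled transcriptomes. Contigs are conceptually translated in
    three (sense) or six frames, open reading frames are scanned for the
    convertase signature of an encoded amidated RFamide
    (Arg-Phe-Gly followed by two basic residues), and surviving candidates are
    annotated as prohormones: a heuristic signal-peptide call, basic-residue
    cleavage sites, Gly-dependent C-terminal amidation, peptide enumeration,
    family classification and tandem-copy counting. Candidates can be named by
    global pairwise identity against a reference precursor set. A synthetic
    transcriptome generator plants precursors with full ground truth so every
    stage of the screen is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
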