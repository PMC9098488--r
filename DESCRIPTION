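Package: minipam
Title: Minimal-PAM CRISPR Target Design and Editing-Efficiency Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide design and quantification toolkit for CRISPR-Cas9
    nucleases with relaxed PAM requirements (SpG recognising NGN, SpRY
    recognising NRN). Enumerates protospacer+PAM sites on both strands of a
    genome for any IUPAC PAM pattern, scores targets with a positional-feature
    on-target activity model applied with the NGG PAM-substitution rule,
    searches and scores off-targets with a CFD score adapted so that
    variant-matching PAMs carry a factor of 1.0, summarises PAM accessibility
    per genomic region class and per CDS, designs fill-in PCR templates for
    in vitro transcription of sgRNAs, and implements the editing-efficiency
    statistics used for zebrafish phenotype assays and C. elegans co-CRISPR
    screens, together with reproducible synthetic fixtures for all of it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
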