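Package: seqsuite
Title: Sequence Manipulation, Motif Search and Pairwise Alignment Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for everyday DNA, RNA and protein sequence
    work: parsing and interconversion of FASTA, GenBank flat file and raw
    sequence text; reverse/complement and collection utilities;
    frame-dependent translation, translation maps, uniform (IUPAC-degenerate)
    and codon-usage-driven reverse translation, and six-frame ORF detection;
    n-gram counts, windowed %GC and protein hydropathy (GRAVY) statistics;
    position-specific frequency matrix (PSFM) construction from site
    collections or IUPAC consensus strings, per-position information content,
    text consensus logos, individual-information (Ri) site scanning, gapped
    and dyad searches with variable spacers, and motif discovery by Gibbs
    sampling or greedy search; global (Needleman-Wunsch) and local
    (Smith-Waterman) pairwise alignment with substitution matrices; plus
    deterministic synthetic-data generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
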