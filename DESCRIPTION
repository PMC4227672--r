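Package: puttier
Title: Homology Tiering, Digital Expression and qRT-PCR Summaries for De
    Novo Insect Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the post-assembly stages
    of a de novo RNA-Seq transcriptome study of the brown marmorated stink
    bug: Phred-based read cleaning with retention accounting, three-tier
    (gold/silver/bronze) homology triage of putatively unique transcripts
    (PUTs) from protein-database alignments, offline UniProt-style
    annotation transfer with term-frequency summaries, digital gene
    expression counting with best-alignment read assignment and
    total-read normalization, pooled pairwise fold-difference comparisons
    with Euclidean-distance reference-gene selection, and 2^-deltaCt
    qRT-PCR summarization. A synthetic-data module generates reads,
    transcripts, alignments, mapping tables and Ct tables with planted
    ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
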