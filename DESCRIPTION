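Package: orthofam
Title: Gene-Family Detection and Pivot-Anchored Orthology Inference for Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics toolkit for identifying a transcription-factor
    family across many proteomes and resolving its orthologous groups. Builds a
    profile hidden Markov model from a seed domain alignment (excluding gapped
    columns) and scans proteomes at a calibrated bit-score threshold; computes
    Smith-Waterman local alignments with affine gaps and Karlin-Altschul bit
    scores; infers orthologs by reciprocal best hits under bit-score and
    coverage filters; assembles pivot-anchored orthologous groups with attached
    paralogs, presence matrices, and basal orthologous groups by n-way
    intersection; annotates members with diagnostic sequence motifs and
    hydropathy-based transmembrane segments; and clusters members into major
    groups with Kimura protein distances, neighbor joining, and bootstrap
    support. A birth-death simulator with whole-genome duplications generates
    proteomes with known evolutionary truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
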