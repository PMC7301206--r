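Package: bescan
Title: Base-Editor Aware Single Guide RNA Design for Microbial Genomes
Version: 0.1.0
Authors@R:
    person("bescan", "developers", email = "bescan@example.org", role = c("aut", "cre"))
Description: Design single guide RNAs (sgRNAs) for CRISPR/Cas9 and
    cytidine/adenine base-editor (CRISPR-BEST style) experiments on
    user-supplied bacterial or fungal genomes.  Finds protospacer
    adjacent motif (PAM) sites over both strands with a suffix array
    built by induced sorting (SA-IS), counts seed-region off-target
    matches at up to three mismatches by bounded-Hamming-distance
    search, simulates deamination within a configurable edit window,
    classifies the resulting codon changes (silent, missense,
    stop-gain), and exports ranked candidate tables as CSV.  Includes a
    deterministic synthetic-genome generator with planted guides,
    off-targets and coding sequences for validation, and a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
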