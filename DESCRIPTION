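Package: enztriage
Title: Triage of Generated Enzyme Coding Sequences Against a Natural
    Reference Set
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-generation triage of machine-generated protein-coding DNA
    sequences for enzyme library design. Provides codon-aware sequence types
    and FASTA/tabular input-output; a codon-level Markov stand-in generator
    with temperature, top-k and nucleus (top-p) sampling; global and local
    pairwise aligners with affine gap penalties, maximum-identity (MaxID)
    novelty scoring and a weighted global/local composite alignment score;
    an ordered filtering pipeline (start codon, length, structure-confidence
    pLDDT gate, novelty, identity binning, ranking, active-site check, greedy
    identity clustering) with stratified per-bin quota selection; multiple
    sequence alignment conservation profiling via per-column Shannon entropy
    and sequence-logo matrices; and detection-call statistics for plate-based
    screening against a negative-control null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
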