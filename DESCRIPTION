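Package: anchorcons
Title: Anchored Consensus Assembly of Tandem Macrosatellite Repeat Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Resolves near-identical tandem macrosatellite repeat arrays
    (D4Z4-like loci) from long, indel-noisy single-molecule reads by
    anchored consensus: reads containing a unique flanking sequence are
    selected, trimmed and orientation-normalized at the flank, stacked
    into a left-anchored multiple alignment, and a consensus is called
    per column by a plurality-above-threshold rule. Includes a
    ground-truth locus and read simulator, repeat-unit segmentation and
    pairwise comparison, dot plots, IUPAC motif scanning, in silico
    restriction digests, copy-number estimation from fragment lengths,
    and read-level quality-control summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
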