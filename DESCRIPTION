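Package: rescaf
Title: Structural Correction and Re-Scaffolding of Draft Genome Assemblies
    with Long Reads
Version: 0.1.0
Authors@R:
    person("rescaf", "developers", email = "rescaf@example.org",
           role = c("aut", "cre"))
Description: A disassemble-reassemble framework for draft genome assemblies.
    Error-corrected single-molecule long reads aligned to a draft assembly are
    used to locate structurally consistent regions, which are extracted as
    validated segments; the segments are then re-ordered and re-oriented by
    solving a maximum weighted alternating path cover on a breakpoint-style
    graph (two vertices per segment, solid edges weighted by bridging-read
    support) with a matching-based 2-approximation, and inter-segment gaps are
    filled with bridging-read subsequences.  Includes a synthetic-data module
    (structurally corrupted drafts, simulated error-corrected long reads), an
    exact brute-force path-cover oracle, and evaluation metrics against the
    simulated truth layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
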