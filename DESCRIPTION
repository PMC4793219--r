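Package: editscan
Title: Detection and Pan-Cohort Analysis of A-to-I RNA Editing from RNA-Seq Variant Calls
Version: 0.1.0
Authors@R:
    person("Maintainer", "editscan", email = "editscan@example.org", role = c("aut", "cre"))
Description: Tools for characterising adenosine-to-inosine (A-to-I) RNA editing
    from RNA-Seq variant calls. Implements a realignment-based artifact removal
    filter (RAAR) that re-places variant-supporting reads under ungapped, gapped
    and spliced local alignment and adjudicates each candidate variant as a true
    call or a named artifact class (multi-alignment, splice-junction, indel);
    quantification of editing sites, events and levels with stringent calling
    followed by relaxed retrieval; cohort recurrence and validation logic;
    paired tumour-normal differential editing with Benjamini-Hochberg FDR
    control and per-gene direction summaries; intersection of editing sites
    with microRNA seed-match intervals, seed-complementarity re-evaluation
    under editing, editing-expression delta correlation, and a four-subtype
    regulatory model; and fully seeded synthetic-data generators with truth
    tables so the whole stack is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
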