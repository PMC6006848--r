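Package: samselect
Title: Sample Sequence Selection for Quorum Planted Motif Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects, from a large DNA dataset, a small sample sequence set
    enriched in motif-bearing sequences so that quorum planted motif search
    (qPMS) becomes tractable. Implements the three-stage selection algorithm
    (mismatch-tolerant word counting over a backward-search index,
    high-frequency substring extraction with attract-table segmentation, and
    affinity-propagation grouping with motif-set validation rules), together
    with a planted (l,d) motif simulator and a small exact qPMS reference
    solver so the whole pipeline can be verified end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
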