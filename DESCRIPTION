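Package: coexsurv
Title: Developmental Co-Expression Modules and Cancer Survival Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking developmental co-expression structure to cancer
    prognosis. Implements a weighted co-expression network core (soft-threshold
    adjacency, topological overlap, average-linkage clustering and a dynamic
    tree cut) with a protein-protein-interaction module filter; per-interaction
    comparison of protein versus mRNA co-expression; module activity scoring
    and early/middle/late stage grouping over a developmental time series; a
    two-cohort Cox proportional-hazards survival screen with median-split
    log-rank testing and a permutation group-enrichment test; and an NCI-60
    style chemoresponse association procedure (mu +/- SD sensitivity
    classification and per gene-drug differential testing). Synthetic-data
    generators with planted ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
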