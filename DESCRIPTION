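Package: panfun
Title: Pangenome-Based Functional Profiles from 16S rRNA Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the functional profile (KEGG Orthology term abundances
    per sample) of a microbial community from a 16S rRNA OTU table. For each
    OTU a pangenome is assembled by pooling functionally annotated reference
    genomes at the OTU's taxonomic lineage, after reconciling the lineage
    against a reference taxonomy and trimming it to the lowest rank with at
    least one genome. Pangenome KO frequencies, normalized by the number of
    pooled organisms, are weighted by 16S copy-number-corrected, sample-size
    normalized OTU abundances to yield a KO-by-sample table. Includes a
    row-resampling bootstrap for percentile confidence intervals on the
    profile, a shared-nonzero Spearman comparison utility, seeded synthetic
    reference databases and OTU tables with exact ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    biomformat,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
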