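Package: sigrev
Title: Drug Repurposing by Transcriptional Signature Reversal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for connectivity-map style drug
    repurposing by signature reversal. Disease differential-expression
    tables are turned into ranked gene lists; a library of drug
    perturbation signatures (up/down gene sets) is scored against each
    ranking with pre-ranked gene set enrichment analysis (weighted
    running-sum statistic, gene-permutation normalized enrichment
    scores); the reversal statistic dNES = NES(down) - NES(up) is
    assembled into a drugs-by-contexts matrix, k-means clustered, the
    cluster with the strongest reversal in every context is selected,
    and recurring target genes are counted from the down-signature
    leading edges. Candidate drugs are verified with a single-sample
    enrichment readout (ssGSEA-style) compared to vehicle control by
    Wilcoxon rank-sum tests. A synthetic-data module generates disease
    signatures, drug libraries and validation expression matrices with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
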