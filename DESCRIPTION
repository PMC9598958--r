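Package: cismeth
Title: Cis DNA Methylation Effects on Gene Expression and Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene penalized regression of gene expression on cis DNA
    methylation (CpG probes within a megabase of the transcription start
    site), with cross-validated elastic-net model selection, coefficient
    importance scoring by TSS distance, CpG-island relation and gene
    component, restricted-window refits, and survival stratification via
    maximally selected log-rank statistics to call methylation-affected,
    survival-associated (MASA) genes. Includes a synthetic-data generator
    with planted regulatory effects so the whole pipeline is testable
    without controlled-access tumor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
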