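Package: socscreen
Title: Transcriptome-Based Drug Repurposing Screen for Chemoresistant Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes per-sample drug sensitivity (log-IC50) from gene
    expression using ridge regression models trained on cell-line
    pharmacogenomic panels, stratifies tumors by predicted response to
    standard-of-care (SOC) chemotherapy, screens for drugs predicted to be
    more effective in SOC-resistant tumors, intersects candidates across
    expression platforms, validates candidates in independent cohorts and
    against measured dose-response AUCs, and runs continuous-phenotype gene
    set enrichment analysis with an opposite-sign pathway filter.  A
    synthetic-data module generates cell-line panels, multi-platform tumor
    cohorts and measured-AUC tables with planted latent-program structure so
    that every stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
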