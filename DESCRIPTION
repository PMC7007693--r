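Package: trisd
Title: Transcriptional Regulator Inference by Chromatin Landscape
    Modeling and In Silico Deletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the transcriptional regulators of a query gene set by
    integrating regulatory-potential models of chromatin signal with in
    silico deletion of candidate regulator cistromes. Chromatin
    accessibility and histone-mark profiles are summarized per gene as
    regulatory potentials with an exponential decay in TSS distance; an
    L1-regularized logistic model selects the profiles that discriminate
    query from background genes; each candidate cistrome is then deleted
    in silico from the selected profiles and the drop in model regulatory
    potential is contrasted between query and background genes by
    one-sided rank-sum tests, combined across evidence channels with the
    Cauchy combination test. Includes genome-wide PWM scanning for
    motif-imputed cistromes, a promoter-count baseline, and a synthetic
    compendium generator with a planted regulator for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
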