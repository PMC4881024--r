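Package: kinorm
Title: Quantification and Normalization of Peptide Microarray Kinome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for radioactive peptide microarray (kinome
    activity profiling) data: spot quantification with quality-based flagging
    from phosphorimager scans, triplicate-based correction of intraslide
    intensity gradients, and an iterative interarray normalization
    ("repetitive signal enhancement", RSE) that local-median-centers a pair
    of arrays on a progressively refined set of condition-unaffected spots.
    Includes an in-silico experiment generator, baseline normalizers
    (median-centering, quantile normalization) and an ROC/AUC evaluation
    harness for benchmarking normalization performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    tiff,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
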