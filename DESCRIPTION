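Package: refstab
Title: Reference-Gene Screening, Stability Ranking and RT-qPCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end identification and validation of RT-qPCR reference
    (housekeeping) genes. Screens genes-by-samples expression matrices
    (RSEM scaled_estimate or TPM) for candidate reference genes by mean
    expression, variance and outlier criteria with CV% ranking; ranks
    candidates by five stability algorithms (CV%, geNorm M-value,
    NormFinder, BestKeeper, comparative delta-Ct) with a RefFinder-style
    consensus by geometric mean of ranks and configurable exclusion rules;
    and performs efficiency-corrected relative quantification of genes of
    interest against multi-gene normalization factors built from all
    k-subsets of the selected references, with calibrator handling and
    normalization-factor outlier checks. Includes a synthetic-data
    generator emulating replicate cultures, consecutive passages and
    normoxia/hypoxia arms so the whole workflow is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
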