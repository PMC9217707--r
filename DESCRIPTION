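Package: permdeg
Title: Permutation-Based Differential Expression for Paired Perturbation
    Designs and Regulator Target Nomination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed genes from paired
    overexpression/knockdown perturbation experiments using a
    ratio-of-ratios paired t-statistic and log2 fold change, with
    empirical null distributions built by sample-label permutation and
    pooled across genes. Includes the unpaired two-sample counterpart for
    case/control senescence datasets, cross-sample quantile
    normalization, multi-dataset intersection with a
    direction-consistency filter for nominating regulator targets,
    2^-ddCt relative quantification of qPCR fold changes, and a
    synthetic-data generator with planted differential expression for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
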