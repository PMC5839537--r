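Package: refstab
Title: Reference-Gene Stability Ranking for RT-qPCR Normalization
Version: 0.1.0
Authors@R:
    person("refstab", "maintainers", email = "refstab@example.org", role = c("aut", "cre"))
Description: Ranks candidate reference (housekeeping) genes for RT-qPCR
    normalization from quantification-cycle (Cq) tables. Implements the three
    stability algorithms in routine use, geNorm gene-stability values (M) with
    iterative exclusion and the V(n/n+1) pairwise-variation series for panel-size
    selection, a NormFinder-style model-based decomposition of intra- and
    inter-group variation, and BestKeeper-style crossing-point descriptive
    statistics, x-fold coefficients and index correlations, together with
    comparative-Cq relative quantification, standard-curve amplification-efficiency
    estimation, a consensus ranking across algorithms, and a synthetic Cq-data
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
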