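Package: lphvm
Title: Robust Co-Clustering of Genes and Doses of Chemical Compounds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Co-clusters genes and doses of chemical compounds (DCCs) in
    toxicogenomic fold-change expression data with a probabilistic hidden
    variable (aspect) model fitted by expectation-maximization. A logistic
    transformation of absolute fold changes bounds the influence of
    outlying expression values, making the co-clustering robust to
    cellwise and rowwise contamination. Includes gap-statistic selection
    of the number of co-clusters, extraction and ranking of biomarker
    genes and their regulatory doses, and a simulation framework for
    benchmarking robustness under Tukey-Huber and independent
    contamination models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
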