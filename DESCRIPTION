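Package: metamediate
Title: Transcriptome-Metabolome Association Meta-Analysis and BMI Mediation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-cohort association analysis of blood transcriptome
    and metabolome data and for mediation analysis towards body mass index.
    Implements study-wise pre-processing (upper-outlier removal, rank-based
    inverse normal transformation, empirical-Bayes batch adjustment, quantile
    normalisation, probe and sample quality filters), per-study linear-model
    association scans with empirical-Bayes variance moderation, hierarchical
    Benjamini-Hochberg false discovery rate control, DerSimonian-Laird
    random-effects meta-analysis with I-squared heterogeneity, a
    product-of-coefficients mediation test against the distribution of the
    product of two standard normal variables with Monte-Carlo confidence
    intervals and proportion-mediated direction classification, bipartite hub
    and mediation network construction, a minimum-detectable-variance power
    calculator, and a synthetic multi-study data generator with planted
    mediation triangles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    limma,
    stats,
    sva,
    tools,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
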