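Package: mppgwas
Title: Comparative GWAS in Structured Multi-Parent Maize Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of quantitative
    traits in structured multi-parent mapping populations (NAM-style
    recombinant inbred families and their backcross and diallel
    derivatives). Implements three complementary association models: a
    single-variant scan with off-chromosome QTL covariates, forward/backward
    stepwise regression, and a BayesC mixture-prior multi-variant Gibbs
    sampler with two-step prior training. Includes composite-interval joint
    QTL mapping with permutation thresholds and 1.5-LOD support intervals,
    a QTL-guided variant thinning and 100-kb binning procedure, and a
    genetic-validation suite (kinship mixed-model tests, pooled
    allele-frequency tests, and a Wright-Fisher drift null for divergently
    selected populations). A synthetic-study generator reproduces the
    statistical structure these analyses assume, so the full pipeline can
    be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    knitr
Config/testthat/edition: 3
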