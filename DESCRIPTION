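Package: transmeta
Title: Cross-Platform Transcriptomic Meta-Analysis of Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-step meta-analysis of differential gene expression across a
    microarray study and an RNA-seq study of the same contrast. Harmonizes the
    two platforms to a shared gene universe, applies platform-appropriate
    normalization (generalized-log plus quantile normalization for intensities,
    log2 counts per million for counts), fits per-study empirical-Bayes
    moderated t-statistics, combines per-gene evidence with Fisher's method
    against a chi-square reference, and calls signed "meta-genes" after
    Benjamini-Hochberg adjustment. Downstream, performs hypergeometric
    over-representation analysis against GMT gene-set collections and ranks hub
    genes in zero- and first-order protein-protein interaction subnetworks by
    degree, betweenness and random-walk-with-restart scores. Includes a
    dual-platform synthetic data generator with known differential-expression
    truth, a parametric empirical-Bayes batch adjustment (ComBat-style) with
    PCA diagnostics, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    limma,
    rmarkdown,
    sva,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
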