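Package: pi1est
Title: Estimating the Proportion of Differentially Expressed Genes and the
    False Discovery Rate in Two-Group Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates pi1, the proportion of differentially expressed
    genes, and the false discovery rate (FDR) in two-group gene expression
    studies.  Implements the SAM s-statistic with a percentile-based
    stabilizing constant and SD/IQR rescaling against the classical
    two-sample t-statistic; pooled permutation null P-values; three pi0
    estimators (a truncated maximum-likelihood empirical-null fit combined
    with a Grenander density, the smoothing-spline mixture-model estimator,
    and the nonparametric MLE under a convex decreasing P-value density);
    and a two-group normal simulation benchmark (EV/UV1/UV2 variance
    regimes) with ROC and bias/variability evaluation of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
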