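Package: qfanova
Title: Permutation Test for Global Differences in Distributions Between
    Groups of High-Throughput Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests whether groups of high-throughput samples (microarray
    intensities, DNA methylation beta values) differ globally in their
    distributions, using an ANOVA-style decomposition of squared Mallow's
    (Wasserstein-2) distances between empirical quantile functions and a
    permutation test on the resulting F statistic. When the test does not
    reject, global-adjustment normalization such as quantile normalization
    is appropriate; the package provides the guarded normalizers (quantile,
    median, spike-in scaling) and a guided selector. Also includes a
    Langmuir-adsorption-model simulator of two-group DNA methylation
    microarray data with configurable differential methylation and
    technical variation, and a Monte Carlo harness evaluating differential
    methylation calling (bias, MSE, false discoveries, TPR/FPR) under
    always-quantile-normalize versus test-guided normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
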