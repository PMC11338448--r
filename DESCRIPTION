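Package: wmwties
Title: Wilcoxon-Mann-Whitney Tests with Tied Observations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact permutation, Monte-Carlo permutation, and tie-corrected
    asymptotic versions of the two-sample Wilcoxon-Mann-Whitney test, with
    explicit handling of tied observations either by mid-ranks on the
    complete data or by omission of all pooled ties before testing. The
    exact null distribution of the rank sum is computed by a
    dynamic-programming shift algorithm over doubled mid-ranks, so exact
    p-values are available for tied data. A simulation engine estimates
    type-I error, power, and post-omission sample sizes for
    rounding-induced ties under normal, exponential, Cauchy, and Laplace
    location-shift alternatives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
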