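Package: rvcluster
Title: Spatial-Kernel Adaptive P-Value Truncation Tests for Rare-Variant
    Association in Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based association tests for rare variants in case-control
    studies. Implements an adaptive P-value truncation statistic that
    incorporates the physical proximity of variant sites through a compactly
    supported spatial kernel (tri-weight), with significance assessed by a
    permutation minimum-P procedure; the identity-kernel special case is the
    adaptive combination of P-values (ADA) test. Also provides the
    Madsen-Browning weighted-sum burden test under the same permutation
    engine, per-site Fisher mid-P and logistic-regression association tests,
    a case-control disease simulator based on a rare-skewed haplotype pool
    with a population-attributable-risk penetrance model, and drivers that
    estimate type-I error and power on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
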