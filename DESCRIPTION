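Package: chsic
Title: Fast Kernel Independence Tests for Cluster-Correlated Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Kernel-based tests of independence between two multivariate
    variables when samples are cluster-correlated (longitudinal visits,
    family members, repeated measures). Implements the Hilbert-Schmidt
    independence criterion (HSIC) and a clustered variant built on
    cluster-wise averaged kernel matrices, with p-values from permutation
    or from a Pearson type III moment-matching approximation whose exact
    permutation moments are computed in closed form. Includes Gaussian
    (median-heuristic bandwidth) and Bray-Curtis kernels, a group-wise
    association screen with Bonferroni correction, and simulation designs
    for size and power studies under Kronecker-structured clustered
    Gaussian data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
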