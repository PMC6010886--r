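Package: ratecomp
Title: Comparing Speciation and Extinction Rates Among Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based comparison of diversification rates between two
    or more time-calibrated phylogenetic trees. Fits a family of nested
    constant-rate birth-death models, conditioned on each tree's crown age and
    allowing known incomplete sampling fractions, in which speciation and/or
    extinction rates are shared or free across trees. Provides likelihood-ratio
    and parametric-bootstrap tests of rate equality, a conditioned reconstructed
    birth-death tree simulator, and scripted simulation experiments measuring
    type-I error, power, and parameter-estimation accuracy of the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    phytools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
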