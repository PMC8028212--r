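Package: countperm
Title: Fast Permutation Testing for Count-Table Interaction Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Permutation testing for SNP-SNP-phenotype interaction measures
    that are functions of 3x3x2 genotype-phenotype count tables, such as
    entropy-based dependence scores. Instead of shuffling phenotype labels
    and re-tallying the raw data at every iteration, the permuted count
    table is sampled directly by iterative hypergeometric draws conditioned
    on the permutation-invariant margins, which reproduces the label
    permutation null exactly at a per-permutation cost independent of the
    number of individuals. Includes a Hardy-Weinberg null data generator,
    plug-in entropy and multi-information estimators, an empirical p-value
    pair scanner, an Epps-Singleton based equivalence validation suite, and
    simple genotype/phenotype/PLINK .raw readers with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    optparse,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
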