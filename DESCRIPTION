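Package: synthrisk
Title: Meaningful Identity Disclosure Risk for Fully Synthetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the identity disclosure risk of fully
    synthetic tabular data. Synthetic records are matched to a population
    through the real sample in both attack directions
    (population-to-sample and sample-to-population), match probabilities
    are attenuated for data errors and imperfect verification using
    correlated triangular distributions, and a match only counts as a
    disclosure when the adversary would learn something new about the
    matched individual for at least a configurable fraction of the
    sensitive variables. An exhaustive search over attack modalities
    (quasi-identifier subsets crossed with generalization hierarchies)
    yields the overall risk, compared against an acceptability threshold.
    Also includes the sequential decision-tree synthesizer such risk
    models are typically applied to, and fixture generators for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    tree,
    yaml,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
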