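Package: modemdr
Title: Multiobjective Differential Evolution MDR for Gene-Gene Interaction
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects SNP epistasis (gene-gene interactions) in case-control
    genotype data by a multiobjective differential evolution search over SNP
    combinations, scored with two multifactor dimensionality reduction (MDR)
    contingency-table measures: the balanced correct classification rate and
    the normalized mutual information.  Nondominated SNP combinations are
    collected in a capacity-bounded Pareto archive.  Includes a penetrance
    table simulator that builds pure (no marginal effect) two-locus epistatic
    models at a target heritability under Hardy-Weinberg equilibrium, an
    exhaustive-search MDR oracle with cross-validation consistency, and a
    detection success rate benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
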