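Package: iutest
Title: Integrative U-Statistic Tests for Joint Association of Sequence
    Variants and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric integrative U (IU) association tests for the joint
    effect of a set of single-nucleotide variants (SNVs) and a gene expression
    measurement on a binary or continuous phenotype. Genotype sequences are
    smoothed into functional curves with penalized natural cubic splines; the
    test statistic averages cross-product phenotype and expression similarities
    weighted by the inner products of the smoothed genotype curves, and is
    standardized by a plug-in null mean and variance derived from the
    functional principal components of the genotype process. Includes a
    genetics-only variant, a three-level extension for an additional omic
    layer, power and minimal sample-size calculators, variance-component
    comparator tests (an expression-adjusted SKAT and a three-component
    variance component test) with mixture-of-chi-squares reference
    distributions, seeded simulation generators for correlated genotype
    panels and null/alternative phenotype models, and an experiment workbench
    for type-I-error and power studies plus a per-gene scan pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
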