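Package: gntrial
Title: Genotype-by-Nitrogen Trial Analysis for Tomato Fruit Quality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of balanced multi-environment variety trials with two
    nitrogen fertilisation levels, built around a 44-accession 'de penjar'
    tomato collection design. Provides derived fruit-quality traits
    (total sweetness index, sugar and acid sums and ratios, carotenoid
    quantification from spectrophotometric absorbances), per-trait
    bifactorial analysis of variance with block removal, variance
    components from expected mean squares, broad-sense heritability and
    coefficients of variation with Delta-method standard errors,
    phenotypic and environmental trait correlations with Bonferroni
    control, principal component analysis with treatment confidence
    ellipses, local-versus-commercial group comparisons, resilience
    indices and accession rankings, and a seeded synthetic-trial
    generator with known variance structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
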