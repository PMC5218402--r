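Package: epiqtl
Title: Epistatic QTL Mapping in F2 Line Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative trait locus (QTL) mapping for F2 crosses between
    two divergent lines, with explicit modelling of epistasis. Provides
    linkage-map arithmetic, a hidden Markov model for line-origin
    probabilities at a 1 cM grid from partially informative multi-allelic
    markers, mixed-model phenotype adjustment with a maternal random effect,
    single-locus and exhaustive two-locus Haley-Knott genome scans with
    permutation-derived significance thresholds, model simplification, and a
    decomposition of epistasis into background-conditional additive and
    dominance effects with standard errors. A synthetic-cross generator
    produces complete studies (pedigree, genotypes, phenotypes) with known
    architecture so every stage of the pipeline can be validated.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
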