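Package: haplodiallel
Title: Diallel Combining-Ability Analysis of Spontaneous Chromosome Doubling in Maize Haploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Griffing Method 1 Model I analysis of full diallel trials for
    haploid male fertility (HMF) and haploid fertility (HF), the traits
    governing spontaneous chromosome doubling in maize doubled-haploid
    production. Computes plot-level traits from fertility counts, the
    combined-environment fixed-effects ANOVA with entry BLUEs, closed-form
    general and specific combining-ability, reciprocal, maternal and
    nonmaternal effects with t tests, the GCA/SCA/reciprocal sum-of-squares
    partition with environment interactions, variance components with
    Baker's ratio and narrow- and broad-sense heritability, and hybrid
    prediction from mid-parent values and summed GCA effects. Includes a
    synthetic full-diallel trial generator with binomial plot-count noise
    and packaged reference tables from a published two-experiment study of
    tropical maize inbreds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
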