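Package: earmap
Title: Fine-Mapping of a Quantitative Trait Locus for Porcine Ear Size in an F2 Intercross
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping and fine-mapping quantitative trait loci (QTL)
    in two-breed F2 intercross designs, motivated by the genetics of ear size
    in Large White x Minzhu pigs. Implements two-step iterative genotype
    quality control (call rate, minor allele frequency, exact Hardy-Weinberg
    test), GRAMMAR residual-based genome-wide association with genomic
    control and Bonferroni thresholds, conditional analysis on a top marker,
    marker-assisted segregation analysis (MASS) of F1 sires via a log10
    likelihood-ratio Z score, linkage-disequilibrium and haplotype analysis
    (EM haplotype frequencies, haplotype score tests, Gabriel-style block
    detection, founder haplotype-sharing segments), and breed-panel
    selective-sweep detection by fixation runs. A synthetic-data generator
    reproduces the statistical structure of the intercross design so that
    every stage of the pipeline can be exercised without access to private
    genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
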