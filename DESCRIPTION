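Package: exburden
Title: Rare-Variant Burden Association Testing at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exome-style rare-variant association studies on
    synthetic cohorts: genotype- and site-level quality control, gene burden
    mask construction with pLOF and deleterious-missense tiers, covariate
    adjusted association tests with a Firth penalized-likelihood fallback for
    binary traits, conditional analysis on common-variant dosages,
    case-control power calculation (empirical simulation and the score-test
    non-centrality parameter), GWAS-locus enrichment combined across traits by
    the Mantel-Haenszel method, a somatic-origin screen based on variant
    allele fraction and age, beta-binomial mixture projection of
    loss-of-function carrier saturation at larger cohort sizes, and
    logistic-curve extrapolation of imputation accuracy versus reference-panel
    size. Includes seeded generators for every input the pipeline consumes, so
    the whole analysis is reproducible without access to individual-level
    biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, methods, vcfR, minpack.lm
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
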