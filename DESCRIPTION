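Package: pedscan
Title: Linkage and Family-Based Association Analysis in Large Extended Pedigrees
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric linkage and family-based association analysis for
    dichotomous and quantitative traits in large multi-generation pedigrees.
    Implements recursive kinship computation, gene-dropping simulation of
    identity-by-descent (IBD) sharing with exact enumeration or Monte Carlo
    estimation of the null IBD-sharing covariance, a weighted affected-relative-
    pair NPL scan with age-difference filtering, a score-based robust linkage
    scan for quantitative traits with covariate and SNP-conditional adjustment,
    maximum-likelihood polygenic and bivariate variance-component models
    (heritability, genetic correlation, measured-genotype association),
    transmission disequilibrium and generalized disequilibrium tests,
    cluster-robust logistic regression, carrier-based screening of rare
    variants with founder allele frequencies and LD pruning, founder
    multidimensional scaling with nonfounder projection, and a simulator of
    extended-family studies with a rare-variant-heavy site frequency spectrum.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, sandwich, withr
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
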