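Package: penmateGWAS
Title: Matched Pen-Mate Case-Control GWAS with McNemar's Test
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association analysis for matched case-control
    designs in livestock, built around McNemar's test on discordant
    pen-mate pairs. Reads PLINK-style ped/map text files with a
    pair-in-family-ID convention, applies minor-allele-frequency,
    missingness and Hardy-Weinberg (exact mid-p) SNP filters, scores
    every SNP under six allele-by-inheritance scenarios (1-copy,
    1-or-2-copy, 2-copy for each allele) with mid-p and exact
    conditional p-values, chi-squared statistics, odds ratios with Wald
    confidence intervals, Cohen's g and a per-marker polygenic risk
    factor value. Provides discrete-p multiplicity control (Bonferroni,
    Storey q-values with bootstrap and cubic-polynomial pi0
    estimation, lattice-aware Q-Q expectations), identity-by-state
    distances with classical multidimensional scaling for population
    substructure screening, a two-locus homozygous-risk classifier
    with prevalence-adjusted predictive values, power analysis for the
    paired design, and a seeded synthetic matched-pair genotype
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
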