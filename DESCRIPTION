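Package: ldlprs
Title: 8-SNP LDL Cholesterol Polygenic Scores and Clinical FH Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of small LDL-cholesterol polygenic risk
    scores built from candidate SNPs, including additive (aPRS) and
    weighted (wPRS) 8-SNP score variants with APOE epsilon-genotype weighting.
    Provides genotype quality control (Hardy-Weinberg equilibrium testing,
    EM-based pairwise linkage disequilibrium with D-prime and r-squared),
    estimation of pre-treatment LDL cholesterol from on-statin measurements,
    Dutch Lipid Clinic Network (DLCN) scoring without genetic items, a
    statistical battery for score-trait association (Spearman, Mann-Whitney,
    Jonckheere-Terpstra trend tests, logistic and linear regression with
    Hosmer-Lemeshow diagnostics, ROC analysis, percentile-extreme risk
    comparisons), a calibrated synthetic genotype-phenotype cohort generator,
    and an end-to-end case-control analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    optparse
Config/testthat/edition: 3
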