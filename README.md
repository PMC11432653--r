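# ldlprs

Construction and case-control association analysis of compact
LDL-cholesterol polygenic risk scores, centred on an 8-SNP score with APOE
epsilon-genotype weighting.

## The problem this package addresses

Most patients with a familial-hypercholesterolemia (FH) phenotype carry no
detectable mutation in LDLR, APOB or PCSK9; in many of them the phenotype
is polygenic — an accumulation of common, small-effect LDLC-raising
alleles. Compact polygenic scores (6–12 SNPs, measurable with ordinary PCR
assays) are the practical tool for quantifying that burden in a clinical
laboratory. `ldlprs` is for researchers and clinical-lab scientists who
want to compute such a score, QC the genotypes behind it, and run the full
association analysis against lipid traits, clinical FH scores and
premature coronary heart disease (PCHD) status in a case-control cohort —
plus a calibrated synthetic-cohort generator so the entire pipeline is
testable without patient data.

## The score

For individual $j$, with $g_{ij}\in\{0,1,2\}$ the count of the *counted*
allele of SNP $i$ and $\varepsilon_j$ the APOE genotype derived from
rs429358/rs7412:

$$\mathrm{aPRS}_j=\sum_{i=1}^{6} g_{ij}+a(\varepsilon_j),\qquad
\mathrm{wPRS}_j=\sum_{i=1}^{6} w_i\,g_{ij}+w(\varepsilon_j)\ \text{[mmol/L]}$$

The six SNPs are LDLR rs6511720, CELSR2 rs629301, APOB rs1367117,
ABCG8 rs4299376, HFE rs1800562 and PCSK9 rs2479409 (weights 0.180, 0.146,
0.105, 0.071, 0.057, 0.052 mmol/L per allele). For the three SNPs whose
minor allele is LDLC-lowering, the common allele is counted as the risk
allele. APOE weights run from −0.800 (ε2ε2) to +0.260 (ε4ε4) mmol/L.
Attainable ranges: aPRS ∈ [−2, 14], wPRS ∈ [−0.800, 1.482] mmol/L.

## Worked example

Score one genotyped patient:

```r
library(ldlprs)
g1 <- genotype_table("patient1", data.frame(
  rs6511720 = 0, rs629301 = 0, rs1367117 = 1, rs4299376 = 2,
  rs1800562 = 0, rs2479409 = 1, rs429358 = 1, rs7412 = 0))
compute_aprs(g1)  # 11
compute_wprs(g1)  # 1.195
```

The wPRS of 1.195 mmol/L decomposes as 2×(0.180+0.146+0.057) for the
common-homozygous nullified trio, +0.105 +2×0.071 +0.052 for the risk
alleles, and +0.130 for the ε3ε4 genotype — a high-burden profile (the
attainable maximum is 1.482).

Simulate a study-sized cohort (125 PCHD cases, 97 controls) and run the
full pipeline:

```r
spec   <- cohort_spec(seed = 7)
co     <- simulate_cohort(spec)
report <- run_full_analysis(co$genotypes, co$phenotypes, seed = 7)
report
#> ldlprs analysis report: 222 individuals (125 cases / 97 controls)
#> SNPs scored: rs6511720, rs629301, rs1367117, rs4299376, rs1800562, rs2479409
#> Tables: score_summary, trait_associations, univariate_models, ...

tab <- report$tables$trait_associations
tab[tab$name %in% c("eldlc_per_sd", "dlcn_ge3_or_per_sd"), ]
#>                name estimate ci_low ci_high       p
#>        eldlc_per_sd   0.1810 0.0503  0.3117 0.00686
#>  dlcn_ge3_or_per_sd   1.4990 1.1310  1.9868 0.00486
```

At this cohort size the pipeline finds what such a design can find: each
+1 SD of the weighted score associates with +0.18 SD of estimated
pre-treatment LDLC, and ~50% higher odds of a DLCN score ≥ 3 (possible or
worse clinical FH). The report bundle also contains the genotype QC
(per-group HWE, LD screen), score-distribution summaries by group,
univariate and multivariate PCHD models with Hosmer–Lemeshow diagnostics,
decile trend tests and DLCN ROC analyses; `write_report_bundle(report, dir)`
serializes everything to CSV plus a JSON manifest. Tail comparisons need
more than 222 individuals to stabilize — at n = 2000 the same generator
yields

```r
co <- simulate_cohort(cohort_spec(n_cases = 1126, n_controls = 874, seed = 7))
extreme_percentile_comparison(compute_wprs(co$genotypes), co$phenotypes$case)
#> risk ratio, extreme percentiles (Katz CI, Fisher p):
#>   estimate = 1.542 (95% CI 1.264-1.881), p = 1.2e-05, n = 405
```

i.e. individuals above the 90th wPRS percentile are ~1.5× more likely to
be PCHD cases than those at or below the 10th.

A thin command-line front end over the same functions lives at
`inst/cli/ldlprs-cli.R` (subcommands `simulate`, `score`, `analyze`).

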