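# il2rameta

Meta-analysis of five common *IL2RA* (CD25) polymorphisms — rs11594656,
rs2104286, rs3118470, rs41295061, rs706778 — and susceptibility to type 1
diabetes (T1D), rebuilt as a tested R package around a packaged study-level
table of 21 outcomes from ten independent case-control studies (32,646
individuals).

It is written for epidemiologists and statistical geneticists who want the
whole chain — per-study allelic odds ratios, Hardy-Weinberg screening,
fixed/random-effects pooling, heterogeneity, influence, publication-bias
tests and false-positive report probability — as auditable, reusable code
rather than a one-off statistics-package session.

## The model

Per study *i*, the minor-allelic log odds ratio and its standard error come
either from the allele-level 2×2 table (Woolf:
`SE = sqrt(1/a + 1/b + 1/c + 1/d)`) or from a published CI
(`SE = (log u − log l)/(2·1.96)`). Pooling is inverse-variance fixed-effect
(`w_i = 1/SE_i²`), with the Mantel-Haenszel/RBG estimator available for
all-counts inputs, or DerSimonian-Laird random-effects with
`τ² = max(0, (Q − df)/(Σw − Σw²/Σw))`. Heterogeneity is Cochran's Q with
`I² = max(0, (Q − df)/Q)·100`; the model selector is disjunctive (random
effects when `p_Q < 0.05` **or** `I² > 50%`). Robustness: leave-one-out
influence with model re-selection, a heterogeneity-targeted sensitivity
scan, Egger regression and Begg-Mazumdar rank-correlation funnel tests, and
Wacholder's false-positive report probability
`FPRP = α(1−π)/(α(1−π) + (1−β)π)` over sceptical priors. The methods
vignette (`vignettes/il2ra-meta-analysis.Rmd`) documents every choice.

A synthetic case-control generator (`simulate_study_set()`) with known true
OR, control MAF, between-study SD τ and optional small-study censoring
backs the calibration checks (null recovery, coverage, funnel-test type-I
error), so every stage is testable without external data.

## Worked example

```r
library(il2rameta)

pool_snp(il2ra_studies("rs41295061"))
#> REM pooled OR (inverse_variance, rs41295061): 0.67 (0.60-0.76), k = 5
#>   Z = -6.52, p = <10^-6
#>   heterogeneity: Q = 9.005 (df 4, p = 0.061), I2 = 55.6%, tau2 = 0.0093

sensitivity_scan(il2ra_studies("rs41295061"))
#> heterogeneity source: omitting 'Klinker' de-triggers (reduced I2 = 0.0%, p_Q = 0.866)
#> FEM pooled OR (inverse_variance, rs41295061): 0.64 (0.59-0.68), k = 4
#>   Z = -12.61, p = <10^-6
#>   heterogeneity: Q = 0.731 (df 3, p = 0.866), I2 = 0.0%, tau2 = 0.0000
```

Reading: the five rs41295061 outcomes are heterogeneous (I² = 55.6%, above
the 50% trigger even though p_Q = 0.061), so the minor allele's protective
pooled OR of 0.67 comes from the random-effects model; the heterogeneity
traces entirely to the Klinker study, without which the association is, if
anything, stronger. The other four SNPs pool by fixed effect: 0.87
(0.83–0.91) for rs11594656, 0.81 (0.77–0.85) for rs2104286, 1.23 (1.16–1.31)
for rs3118470 and 1.20 (1.08–1.33) for rs706778 — all five SNPs associate
with T1D, protective or risk according to which allele is tagged.

## The analysis workflow

The numbered drivers under `analysis/` run the full study end to end,
writing TSV/JSON tables (plus run manifests) under `results/`:

```sh
Rscript analysis/01_pool.R               # per-SNP pooled table, weights, forest data
Rscript analysis/02_influence.R          # leave-one-out + sensitivity scan
Rscript analysis/03_publication_bias.R   # Egger/Begg + funnel data
Rscript analysis/04_fprp.R               # FPRP grids over sceptical priors
Rscript analysis/05_simulation_checks.R  # calibration on synthetic study sets
```

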