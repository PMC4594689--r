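---
title: "Methods: meta-analysis of IL2RA polymorphisms and type 1 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of IL2RA polymorphisms and type 1 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(il2rameta)
```

## The scientific question

The interleukin-2 receptor alpha gene (*IL2RA*, CD25) sits in one of the
best-replicated non-HLA susceptibility regions for type 1 diabetes (T1D).
Five independently tagged common SNPs — rs11594656, rs2104286, rs3118470,
rs41295061 and rs706778 — have each been tested in case-control samples, with
inconsistent single-study results. This package pools those study-level
results: per-SNP odds ratios under the minor-allelic comparison, combined by
fixed-effect or random-effects meta-analysis, followed by the standard
robustness battery (heterogeneity metrics, leave-one-out influence,
funnel-asymmetry tests, false-positive report probability).

The packaged study table (`il2ra_studies()`) holds 21 study outcomes from ten
independent studies (32,646 individuals): per-outcome genotype counts where
the source printed them, otherwise the reported OR with its 95% CI.

## Data model and effect extraction

Each row is a `study_outcome`: identity (study, year, country, ancestry),
SNP, design, and either genotype counts for both groups
(major-hom/het/minor-hom, the `"a/b/c"` convention) or a reported OR with
both CI bounds. Validation is strict and row-numbered; a row with neither
source of effect information is rejected outright.

Two extraction routes produce the `effect_estimate` (log OR + SE) that every
downstream stage consumes:

* **From counts** (`effect_from_counts()`): each person contributes two
  alleles, giving a 2×2 allele table; the Woolf estimator provides
  $\hat\theta = \log\frac{ad}{bc}$ and
  $\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$. A zero cell triggers the
  Haldane–Anscombe +0.5 correction on all four cells (with a warning); two or
  more zero cells make the effect inestimable.
* **From a reported CI** (`effect_from_ci()`):
  $\mathrm{SE} = (\log u - \log \ell) / (2z)$.

**Why $z = 1.96$ and not `qnorm(0.975)`.** Published tables print two
decimals and are produced by software using the rounded quantile; the
packaged table's pooled results reproduce exactly under 1.96. The quantile is
an explicit argument everywhere, so the four-decimal quantile is one keyword
away.

**Why reported ORs are the default effect source.** Several printed ORs are
*not* the Woolf allelic ORs of their printed counts — e.g. the Kawasaki
rs11594656 row prints 0.91 (0.59–1.41) where the counts give ≈0.87, and the
Kawasaki rs706778 row prints the major-allele contrast (its printed MAF
exceeds 0.5 in cases). The source studies evidently adjusted or used
different denominators, and the published pooled values combine the printed
numbers. Taking printed values at face value (`effect_source = "reported"`)
reproduces the published synthesis; `effect_source = "counts"` recomputes
everything from genotypes for users who prefer raw-data consistency. The
rs706778 orientation is handled by an explicit `orientation = "major"` flag
on that row rather than by guessing the source's intent.

**MAF cross-check.** Where counts and a printed MAF coexist, the recomputed
frequency is compared at three decimals; a mismatch warns but does not fail,
because the Lowe set-1 rows demonstrably used the printed totals (which
exceed the genotyped totals) as denominators.

## Hardy–Weinberg screening

Control genotype distributions are tested against HWE with the 1-df Pearson
chi-square at the sample allele frequency; the screen excludes outcomes whose
controls depart at $p < 0.05$ (case-control) or $p < 10^{-5}$ (GWAS panels,
where tiny deviations reach significance on huge samples). Cases are not
screened — a true association itself distorts case genotype frequencies.
Monomorphic samples are defined as non-departing (chi-square 0). All packaged
control samples pass.

## Pooling

Fixed-effect pooling uses inverse-variance weights
($w_i = 1/\mathrm{SE}_i^2$). The classical Mantel–Haenszel stratified
estimator (with the Robins–Breslow–Greenland variance) is provided for
all-counts inputs, but cannot handle CI-only rows, of which the packaged
table has eight; the inverse-variance path is therefore the canonical
fixed-effect route, and on the all-counts subsets the two agree to well
under 0.005 on the OR scale (asserted in the tests).

Random-effects pooling is DerSimonian–Laird:
$\hat\tau^2 = \max\!\big(0, (Q - df) / (\textstyle\sum w - \sum w^2 / \sum w)\big)$,
re-weighting by $1/(\mathrm{SE}_i^2 + \hat\tau^2)$.

Heterogeneity is Cochran's $Q$ with $I^2 = \max(0, (Q - df)/Q) \cdot 100$.
The **model selector is disjunctive**: random effects when $p_Q < 0.05$
*or* $I^2 > 50\%$. The disjunction matters: the rs41295061 set has
$p_Q = 0.061$ yet $I^2 = 55.6\%$, and it is the $I^2$ trigger alone that
selects the random-effects model there.

The pooled effect is tested by a two-sided normal Z-test; summary tables
print p-values below $10^{-6}$ as `<10^-6`. Summed case/control counts are
the column sums of the packaged rows; for rs11594656 this gives 12,963
controls where the published total prints 12,956 (a 7-person discrepancy in
the source's own arithmetic) — the package reports its own sum.

## Influence and sensitivity

`leave_one_out()` re-pools after dropping each outcome in turn, re-applying
the model selector, and flags omissions that change the model or flip
significance ("the 95% CI crosses 1 in exactly one of full/reduced" — the
operational reading of a study "excessively influencing" the result).
`sensitivity_scan()` runs only when the full set triggers the heterogeneity
rule and reports the omission that de-triggers it with the least residual
heterogeneity (ties broken by $Q$). On the packaged data: omitting Maier
from rs2104286 moves the pooled OR to 0.89 (0.76–1.03) — significance lost —
and omitting Klinker from rs41295061 eliminates the heterogeneity
($I^2 = 0$, $p_Q = 0.87$) while the association stands.

## Publication bias

`egger_test()` regresses standardized effects on precision (OLS; intercept
t-tested on $k-2$ df). `begg_test()` rank-correlates the variance-stabilized
deviates with the variances, using the Kendall score with tie-corrected
variance. The "modified" Begg variant is taken to be the continuity-corrected
score, the common implementation default, with `continuity = FALSE`
available. At small $k$ the corrected variant is markedly conservative — the
exact permutation null at $k = 6$ rejects at $12/720 \approx 1.7\%$ — while
the uncorrected score sits essentially at nominal level
($40/720 \approx 5.6\%$); the calibration checks in the test suite therefore
assert nominal type-I error for the uncorrected score and conservatism for
the corrected one. Egger's test at $k = 3$ has one residual degree of
freedom; its p-values on three-study sets are reported but fragile.

Funnel plots (and forest plots) are emitted as plain data tables; rendering
is deliberately outside the computational core so no numeric result depends
on graphics.

## False-positive report probability

For a pooled result, FPRP
$= \alpha(1-\pi) / \big(\alpha(1-\pi) + (1-\beta)\pi\big)$ where $\alpha$ is
taken as the *observed* two-sided pooled p-value (the grid is about one
specific result, not a generic level — configurable), $1-\beta$ is the
two-sided Z-test power at an alternative OR computed from the pooled SE, and
$\pi$ ranges over sceptical priors (default 0.25 down to $10^{-5}$).
Alternative ORs default to 1.2 and 1.5 plus the observed pooled OR, since no
canonical alternative exists for these SNPs; cells below 0.2 are flagged
noteworthy. Power at extreme $\alpha$ (below $\sim 10^{-12}$) inherits the
precision of the normal quantile/tail round trip; the identity
power$(\mathrm{OR}=1) = \alpha$ is exact only away from that extreme tail.

## The synthetic-study generator

`simulate_study_set()` is the stand-in for raw data: it draws per-study true
log ORs from $N(\log \mathrm{OR}, \tau^2)$, converts the control minor-allele
frequency $p_0$ to the case frequency
$p_1 = \mathrm{OR}\,p_0 / (1 + p_0(\mathrm{OR} - 1))$ (multiplicative
allelic model — the simplest model consistent with an allelic OR analysis),
and samples genotypes multinomially under HWE at each frequency.
`reporting_mode = "ci_only"` replaces counts with the Woolf OR/CI rounded to
two decimals, deliberately mimicking journal-table precision so the
CI-derived-SE path is stress-tested against rounding noise. Optional
censoring implements the one-sided file-drawer model: studies whose signed
$\hat\theta/\mathrm{SE}$ falls below a cutoff are suppressed with a given
probability, optionally only below a size threshold (large studies always
publish) — the size-dependence is what tilts the funnel.

Generator defaults — five studies of 1000/1000 at control MAF 0.30,
homogeneous null — describe a typical mid-size candidate-gene replication
set, the scale of the packaged studies. The calibration null funnel uses
$k = 6$ with group sizes on a geometric ladder from 200 to 1800 (a 3-fold SE
spread) so the asymmetry regressions have leverage.

What the generator does **not** emulate: genotyping error, linkage
disequilibrium between SNPs, covariate adjustment or stratified sampling,
and the source-specific adjustments that make some printed ORs differ from
their counts. Passing recovery tests therefore validates the estimators
under the sampling model, not the provenance quirks of any real table.

## Numerical choices and degenerate inputs

* $I^2$ truncates at 0 and is reported in percent to one decimal.
* $\hat\tau^2$ truncates at 0; at $Q \le df$ random effects equals fixed
  effect to machine precision (asserted at $10^{-12}$).
* Zero allele cells: +0.5 to all four cells, warned; two or more zero cells:
  error.
* Begg deviates with non-positive conditional variance (extreme weight
  concentration) use the absolute value, with a warning.
* Egger on identical SEs: error (degenerate design).
* Pooling a single outcome returns that effect flagged `single_study`;
  fewer than three outcomes per SNP warns (the design minimum) without
  refusing.
* All validation failures and computation failures raise distinct condition
  classes (`il2rameta_validation_error`, `il2rameta_computation_error`),
  which the analysis drivers map to distinct exit codes.

## Known limitations

* **DL undercoverage at small $k$.** The z-based DerSimonian–Laird interval
  is known to undercover when few heterogeneous studies are pooled, because
  $\hat\tau^2$ is noisy and the interval ignores that noise. The test
  suite's coverage check computes this directly: at $k = 5$, $\tau = 0.1$,
  2000/2000 per study (between-study variance ≈ 4× within-study), measured
  coverage sits near 89–90%, short of nominal. Remedies such as the
  Hartung–Knapp adjustment are deliberately out of scope; the package
  reports both models and their agreement instead.
* Ethnicity-stratified pooling is not offered: only two Asian study sets
  exist in the packaged table, too few to stratify.
* Haplotype effects are not assessable from study-level summary data.
* Alternative $\tau^2$ estimators (REML, Paule–Mandel), trim-and-fill, and
  Peters'/Harbord's tests are out of scope.

## Problem sizes used by the checks

The test suite uses 2000 replicates for HWE p-value uniformity, 5000 for the
$I^2$ exceedance rate and for funnel-test type-I error, 500 for DL coverage,
and 300 for the censoring demonstration; the `analysis/05_simulation_checks.R`
driver repeats the same checks at 150–1000 replicates. These sizes put
Monte-Carlo error well inside the asserted bands while keeping each run in
minutes on one core.
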