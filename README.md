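# famliab

Family-based inference for binary disorders in multi-generation population
cohorts: familial aggregation and coaggregation via marginal recurrence
risk ratios, family-clustered tetrachoric correlations, and
liability-threshold familiality and familial-correlation estimation, with
a synthetic three-generation cohort generator for validation by parameter
recovery.

## Who this is for

Epidemiologists and genetic epidemiologists analysing cohorts in which
whole families are enrolled and every member's disease status is assessed
directly (no proband reports, no registry linkage). The package covers the
standard analysis chain for such data, with family clustering respected in
every uncertainty statement.

## The statistics at the core

**Recurrence risk ratio.** For a relative class R (first-degree, siblings,
parents, offspring, second-degree, spouses),
λ_R = P(disease | affected relative of class R) / P(disease), estimated by
g-computation: a logistic model of status on the affected-relative
indicator (adjusted for age, age², sex, and the number of relatives in the
data) is averaged over the cohort's covariate distribution twice — as
observed, and with exposure set to one for everyone. The ratio of the two
plug-in means is λ_R; its Wald interval uses the family-clustered sandwich
covariance and the delta method.

**Tetrachoric correlation.** Relatives' binary statuses are modelled as
dichotomized bivariate-normal liabilities; the two-step MLE fixes
thresholds at the margins and maximizes the 2×2 multinomial likelihood in
the latent correlation. Standard errors come from a cluster bootstrap over
nuclear families (pairs are double-entered where symmetric; trios
contribute two pairs sharing a cluster).

**Familiality and familial correlation.** Under the liability-threshold
model with threshold t = Φ⁻¹(1−K) and selection intensity i = φ(t)/K, the
prevalence K_R among relatives of affected probands identifies the
pairwise liability correlation ρ through the Reich-corrected relation
t_R = (t − ρi)/√(1 − ρ²·i(i−t)); familiality is h_f = ρ/a_R with a_R the
relatedness weight (0.5 first-degree, 0.25 second-degree). The
cross-disorder version selects probands on disorder a and thresholds
relatives on disorder b, giving r_f = ρ_cross/(a_R·√(h_a·h_b)). Exact
bivariate-normal forward and inverse calculators are included as oracles
for the approximation; intervals are percentile cluster bootstraps.

## Worked example

Simulate a cohort of 20,000 families with two disorders — a common one
("MDD", prevalence 17%, familiality 0.30) and a rarer one ("CFS", 5%,
familiality 0.42) — sharing a familial correlation of 0.83, then run the
analysis chain:

```r
library(famliab)

cfg <- sim_config(
  n_families    = 20000,
  disorders     = c("MDD", "CFS"),
  prevalence    = c(0.17, 0.05),
  familiality   = c(0.30, 0.42),
  familial_corr = matrix(c(1, 0.83, 0.83, 1), 2),
  spousal_corr  = c(0.15, 0.10),
  seed          = 2026)
cohort <- simulate_cohort(cfg)
pairs  <- relative_pairs(build_pedigree(cohort))

xt  <- exposure_table(cohort, pairs, "CFS", relative_class = "first-degree")
marginal_lambda(fit_disease_model(xt))
#>   exposure outcome relative_class lambda ci_low ci_high    se  p_pop p_exposed
#> 1      CFS     CFS   first-degree   2.23   2.07    2.39 0.082 0.0502     0.112
#>   n_total n_exposed
#> 1   84427      9605
```

Having an affected first-degree relative multiplies CFS risk by 2.23
(95% CI 2.07–2.39): the standardized prevalence rises from 5.0% to 11.2%.

```r
sib <- pairs[pairs$relationship == "full-sibling", ]
clustered_tetrachoric(sib, cohort, "MDD", "CFS", B = 200, seed = 1)
#> Tetrachoric rho = 0.1395 (thresholds 0.954, 1.651; n = 45034)
```

The cross-disorder cross-sibling liability correlation is 0.14, close to
its generative value 0.5·√(0.30·0.42)·0.83 = 0.147.

```r
familiality_estimate(cohort, pairs, "CFS", B = 200, seed = 1)
#>   disorder degree   h_f falconer ci_low ci_high     se    K   K_R
#> 1      CFS  first 0.456     0.43  0.407   0.498 0.0246 0.05 0.115
```

CFS prevalence among first-degree relatives of cases is 11.5% against
5.0% overall, which the Reich-corrected estimator converts to a
familiality of 0.46 (95% CI 0.41–0.50; generative truth 0.42).

```r
familial_correlation_estimate(cohort, pairs, "MDD", "CFS", B = 200, seed = 1)
#>     r_f ci_low ci_high   h_a   h_b
#> 1 0.785  0.697   0.865 0.302 0.456
```

The familial correlation estimate 0.79 (95% CI 0.70–0.87) recovers the
generative 0.83 within its interval.

An end-to-end run — λ_R matrices for several relative classes, sibling and
parent-offspring tetrachoric matrices, familiality and familial
correlation tables, participation regressions, CSV outputs and a JSON
manifest — is one call:

```r
run_all(list(simulation = list(n_families = 20000,
                               prevalence = c(0.17, 0.05),
                               familiality = c(0.30, 0.42)),
             boot = 500, seed = 1, out_dir = "results"))
```

A thin command-line wrapper with subcommands (`simulate`, `pairs`,
`lambda`, `tetrachoric`, `familiality`, `famcorr`, `participation`,
`run-all`) is installed at `inst/cli/famliab.R`.

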