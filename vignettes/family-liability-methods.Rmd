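---
title: "Family-based aggregation and liability-threshold familiality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based aggregation and liability-threshold familiality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famliab)
```

## The scientific problem

Large population cohorts that enrol whole families — parents, siblings,
offspring, sometimes three generations — allow the familial component of
common binary disorders (mood and anxiety disorders, functional somatic
disorders, and the like) to be quantified without relying on proband
reports of relatives' health or on registry diagnoses. famliab implements
the standard analysis chain for such data:

1. **Familial aggregation and coaggregation** via the recurrence risk
   ratio $\lambda_R$: the prevalence of a disorder among relatives of
   affected persons divided by the population prevalence.
2. **Tetrachoric correlations** between relatives' statuses, which, unlike
   $\lambda_R$, are insensitive to prevalence differences across
   disorders.
3. **Familiality** $h_f$ — the proportion of liability variance
   attributable to familial effects (genetic and shared-environmental
   combined; family data alone cannot separate the two) — and
   **familial correlations** $r_f$ between disorders, both under the
   liability-threshold model.

A synthetic cohort generator produces three-generation family data with
known familiality, familial correlations, spousal resemblance and
selective dropout, so every estimator can be validated by parameter
recovery.

## The liability-threshold model

Each person carries, per disorder $p$, a latent liability
$L_p \sim N(0, 1)$; the person is a case iff $L_p > t_p$, where
$t_p = \Phi^{-1}(1 - K_p)$ and $K_p$ is the population prevalence.
`liability_model(K)` returns the threshold $t$, the normal density $z$ at
$t$, and the selection intensity $i = z/K$ — the mean liability of
affected individuals. Relatives' liabilities are bivariate normal with
correlation $\rho = a_R h_f$, where the relatedness weight $a_R$ is 0.5
for first-degree and 0.25 for second-degree relatives.

### Familiality from prevalences (Falconer / Reich)

Given the population prevalence $K$ and the prevalence $K_R$ in relatives
of affected probands, Falconer's first-order estimator of the liability
regression is $b = (t - t_R)/i$ with $t_R = \Phi^{-1}(1 - K_R)$. The
Reich–James–Morris correction accounts for the reduced variance of
liability in relatives of selected probands: the relative's liability
given proband affection is approximately normal with mean $\rho i$ and
variance $1 - \rho^2 k$, $k = i(i - t)$, so

$$t_R = \frac{t - \rho i}{\sqrt{1 - \rho^2 k}}.$$

`reich_familiality()` inverts this relation for $\rho$ in closed form
(the classic corrected expression) and reports $h_f = \rho / a_R$, with
the Falconer value alongside as a diagnostic. The same relation with the
proband's threshold and selection intensity taken from disorder $a$ and
the relative's threshold from disorder $b$ yields the cross-disorder
liability correlation $\rho_{cross}$; the quadratic inversion used for it
reduces exactly to the classic same-trait formula when $a = b$. The
familial correlation is then

$$r_f = \frac{\rho_{cross}}{a_R \sqrt{h_a h_b}},$$

clipped to $[-1, 1]$ with a flag when sampling noise pushes it outside.

### Exact oracles

Because the Reich expression is an approximation, the package carries the
exact computation as an oracle: `exact_relative_prevalence(rho, K_p, K_r)`
integrates the bivariate-normal orthant directly, and `exact_rho()`
inverts it by bracketed root finding. Across $K \in [0.01, 0.2]$,
$h \in [0.05, 0.6]$ and both $a_R$ values the Reich-corrected estimator
agrees with the exact inversion to within 0.02 (asserted in the test
suite). The orthant probability itself is evaluated by 48-node
Gauss–Legendre quadrature of the arcsine-substituted single-integral
identity, which is smooth and bounded over the whole correlation range,
including near $\pm 1$.

### Which conditional prevalence?

$K_R$ is estimated **pair-wise**: over all double-entered relative pairs
of the chosen degree, the share of pairs with an affected relative among
pairs with an affected proband. This estimates
$P(\text{relative affected} \mid \text{proband affected})$, which is the
quantity the threshold relation above is written for. The seemingly
equivalent person-level alternative — the prevalence among persons with
*at least one* affected relative — conditions on a different event and is
biased low when persons have several relatives (conditioning on "$\ge$ 1
of $m$ relatives affected" selects less extreme family liabilities than
conditioning on a specific affected relative); simulation confirms a
recovery of 0.39 instead of 0.42 under the person-level definition. The
$\lambda_R$ machinery, whose target *is* the person-level contrast, uses
the person-level exposure; the familiality machinery uses pair-based
prevalences.

### Degrees and their combination

First-degree pairs are parent–offspring and full siblings; second-degree
pairs are half-siblings, grandparent–grandchild and avuncular pairs
(aunt/uncle–niece/nephew). Per-degree estimates are combined by
inverse-variance weighting with variances taken from the cluster
bootstrap. Cross-disorder estimates are computed in both proband
directions ($a$-probands scored for $b$ in relatives, and vice versa) and
averaged, since neither direction is privileged; their bootstrap
distribution is computed on the same resamples.

## Recurrence risk ratios by marginal standardization

For a disorder pair (exposure, outcome) and a relative class,
`exposure_table()` marks each person as exposed iff at least one relative
of the class is a case **by the relative's own record** (proband reports
are never used). Persons without relatives of the class in the data stay
in the table unexposed — they inform the population prevalence — and the
number of relatives with known status enters the model as a covariate,
since family size in the data is associated with both exposure and
outcome. Relatives with missing status create no exposure and are not
counted: exposure must be ascertained, not imputed.

`fit_disease_model()` fits the logistic regression

$$\text{logit } P(Y = 1) = \beta_0 + \beta_1 \text{exposed} +
\beta_2 \text{age}_c + \beta_3 \text{age}_c^2 + \beta_4 \text{sex} +
\beta_5 n_{rel},$$

with age centred before squaring (this reduces collinearity without
changing fitted values) and coefficient covariance from the clustered
sandwich estimator with families as clusters. Spouse analyses replace
$n_{rel}$ with the presence-of-spouse indicator. `marginal_lambda()` then
standardizes: $p_{pop}$ is the mean predicted probability at observed
covariates, $p_{exp}$ the mean prediction with everyone's exposure set to
1, and $\lambda_R = p_{exp}/p_{pop}$. The 95% interval is Wald on the
ratio scale, with the gradient of the ratio in the coefficients obtained
by central differences and propagated through the clustered covariance.
With an exposure-only model the plug-in means reproduce the stratum means
exactly, so $\lambda_R$ equals the crude prevalence ratio — an identity
the test suite asserts to $10^{-10}$.

## Tetrachoric correlations

`tetrachoric_mle()` uses the standard two-step estimator: thresholds fixed
at the normal quantiles of the margins, then the single free correlation
maximizing the multinomial likelihood of the 2×2 table. Numerical
choices: a zero cell adds 0.5 to every cell (flagged); estimates beyond
|0.999| are reported as ±1 with a boundary flag rather than an error;
the optimizer works on $[-0.9999, 0.9999]$ with tolerance $10^{-9}$. The
test suite checks the estimator against an independent brute-force grid
search (step $10^{-4}$) that accumulates the orthant probability by
trapezoidal integration of a different integral representation, and
against the closed form $P_{11} = \tfrac14 + \arcsin(\rho)/2\pi$ at
50/50 margins.

Sibling tables and same-disorder tables are double-entered (each pair in
both orders), which leaves the point estimate of a symmetric table
unchanged and only matters for clustering; cross-disorder
parent–offspring tables are double-entered over both role assignments so
a single symmetric matrix is reported. Uncertainty comes from a cluster
bootstrap over nuclear families (`clustered_tetrachoric()`, default
B = 500): both orderings of a pair, and both pairs of a parent–offspring
trio, move with their cluster. The bootstrap replaces the analytic
weighted-least-squares corrections of latent-variable software; it is
assumption-light and correct under within-family dependence.

## The synthetic cohort generator

`simulate_cohort()` draws families from configurable templates (couples
with 1–3 children; with configurable probability the eldest child gains a
spouse and one or two children, extending the family to three
generations; defaults 35/45/20% for sibship sizes and 15% third-generation
share, a typical population-cohort shape). Per family the stacked
liabilities over members × disorders have covariance

$$\Sigma = A \otimes F + I \otimes E + S \otimes \mathrm{diag}(s),$$

with $A$ the relatedness matrix, $F_{pq} = \sqrt{h_p h_q}\, r_f(p,q)$ the
familial covariance, $E_{pq} = \sqrt{(1-h_p)(1-h_q)}\, r_e(p,q)$ the
residual covariance and $s$ the per-disorder spousal liability
correlation between spouse rows ($S$). Every liability has unit total
variance, so sibling concordance is exactly $0.5 h_f$ on the liability
scale. $\Sigma$ is verified positive semidefinite and rejected otherwise
with its smallest eigenvalue reported (an overlarge spousal term is the
typical cause).

Deliberate modelling choices:

* **Spousal resemblance is phenotypic and non-transmitted** — a direct
  liability correlation between spouses, not assortative mating passed to
  offspring. Family data cannot distinguish assortment from shared
  environment, so the simpler mechanism is generated.
* **Sex and age effects** enter as liability mean shifts (female–male
  contrast; linear + quadratic in standardized age); the threshold is
  then recalibrated by root-finding over the realized covariate pool so
  the marginal prevalence still equals the target $K$.
* **Waves and missingness.** Wave 1 participation is complete; waves 2
  and 3 are Bernoulli at configurable base rates (defaults 0.80 and
  0.75). A disorder's status is observed iff the person participated in
  at least one wave assessing it; the aggregated case definition is
  "case in any participated wave". `apply_selective_dropout()` redraws
  later-wave participation from a logistic model with coefficient
  $\log(\mathrm{OR})$ on having an affected first-degree relative,
  preserving the base rate for the unexposed; the default generative OR
  in the dropout sensitivity analysis is 0.86, and
  `participation_model()` recovers it within ±0.03 at 100,000 persons.
* **Auxiliary flags** for the sensitivity analyses: a somatic-comorbidity
  flag (prevalence 25% in cases, 5% in controls by default), and per-case
  symptom duration (75% reach six months) and interference with daily
  activities (80%), so severity alignment retains 60% of cases by
  default.

All randomness flows from the single seed, and the generator restores the
caller's RNG state; identical configurations reproduce byte-identical
tables.

What the generator does **not** emulate: symptom-level diagnostic
instruments (status is emitted directly), onset timing and time-varying
prevalence, transmitted assortative mating, non-normal liabilities, and
real cohorts' heterogeneous family structures beyond the configured
templates. Passing recovery tests therefore show the estimators are
correct under the model they assume, not that real data satisfy that
model.

## Confidence intervals and calibration

Familiality and familial-correlation intervals are percentile cluster
bootstraps over families (default B = 200 in the estimators, B = 500 in
the pipeline; the family-level sufficient counts make replicates cheap).
$\lambda_R$ intervals are delta-method Wald. Under null simulations
(familiality 0) with 2,000 families per replicate, both interval types
achieve 92–98% empirical coverage over 200 replicates in the test suite.
Familial correlations have their intervals truncated to $[-1, 1]$;
negative familiality estimates are flagged but not clipped, so simulation
studies can detect bias.

## Problem sizes

The validation suite uses 50,000 nuclear families for parameter-recovery
checks (recovery within ±0.04 for $h_f$, ±0.05 for $r_f$), 20,000–30,000
families for generator-level concordance checks, 2,000 families × 200
replicates for coverage, and 25,000 families for the dropout-OR recovery;
these sizes make Monte-Carlo error comfortably smaller than the asserted
tolerances while keeping the default test run inside a few minutes.

## Known limitations

* The Reich-style estimators assume a strictly normal liability; the
  exact oracles share that assumption and only validate the
  approximation, not normality itself.
* Ascertainment is assumed population-based; no correction for
  clinic-based sampling is provided.
* Relationship classification is confined to the analysed classes
  (parent–offspring, full/half siblings, grandparent–grandchild,
  avuncular, spouse); cousins and step/in-law relations return "none"
  and first-degree classes are biological only.
* The pairwise Reich inversion treats each relative pair marginally;
  no joint pedigree likelihood is attempted.
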