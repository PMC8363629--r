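---
title: "Differential GWAS between two disorders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential GWAS between two disorders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddx)
```

## The problem

Psychiatric disorders are routinely studied one at a time against healthy
controls, yet the clinically pressing question is often *differential*: given
that a patient has either schizophrenia or major depression, which one is it,
and do common genetic variants carry information about that distinction?
`ddx` estimates per-SNP **differential associations** between two disorders
using nothing but each disorder's case-control GWAS summary statistics,
then quantifies how well a polygenic score built from those statistics could
separate the two patient groups.

## The differential association model

Write the per-allele log-odds of disorder 1 and disorder 2 for SNP dosage
$S$ as $\beta_{11}S$ and $\beta_{12}S$ (intercepts and error terms play no
role in what follows because they cancel in the contrast). If the controls
of both studies are drawn from the same population, the odds ratio of
disorder 1 *versus* disorder 2 satisfies

$$\mathrm{OR}(T_1\ \mathrm{vs}\ T_2) = e^{\beta_{13}},\qquad
\beta_{13} = \beta_{11} - \beta_{12},$$

so a "case-case GWAS" can be synthesized as the difference of the two
studies' effect estimates. Its variance is

$$\mathrm{Var}(\beta_{13}) = \mathrm{Var}(\beta_{11}) +
\mathrm{Var}(\beta_{12}) - 2\,\mathrm{Cov}(\beta_{11},\beta_{12}),$$

where the covariance is nonzero whenever the two studies share subjects
(in practice, shared controls). `differential_effect()` parameterizes the
covariance as $r_\mathrm{int}\,\mathrm{SE}_1\,\mathrm{SE}_2$ with
$r_\mathrm{int}$ the **cross-trait LD-score-regression intercept**, which
estimates exactly this error correlation from summary data. Ignoring the
term wastes power: with positively correlated errors the differential test
becomes conservative (the simulation below shows type-I error dropping from
the nominal 5% to about 2% at a 25% control overlap).

Two equivalent sources for $r_\mathrm{int}$ are supported: `ldsc_rg()`
estimates it from the z-score products, and `overlap_intercept()` computes
the analytic value $n_\mathrm{shared}\sqrt{p_1p_2/(q_1q_2)}/\sqrt{n_1n_2}$
implied by a known number of shared controls (for two equally sized studies
with 50% case fractions this is simply the overlap rate). The analytic form
follows from the covariance of the two per-SNP score statistics over the
shared subjects.

### Genomic control

After the differential test, residual stratification is guarded against by
genomic control: the $\chi^2$ statistics are divided by an inflation factor
$\lambda$, taken either from the intercept of an LD-score regression on the
differential statistics (`gc = "ldsc"`), from the median $\chi^2$ divided
by 0.4549 (`gc = "median"`), or supplied directly. $\lambda$ is clamped at
1 — deflation is never applied, following standard practice. Genomic
control affects only the reported p-values; heritability fits consume the
uncorrected statistics.

## Harmonization

`harmonize_pair()` joins the two studies on SNP ID and re-aligns study 2 to
study 1's effect allele: swapped alleles flip the effect sign and
complement the allele frequency, strand-complemented records are
complemented first. A/T and C/G (palindromic) SNPs cannot be disambiguated
from allele labels; the default policy drops them, and the optional
frequency-informed policy keeps them only when both studies report
frequencies outside $0.5 \pm 0.08$ on the same side. The window of 0.08 is
a deliberately conservative default — with a tight window a strand error at
a near-0.5-frequency SNP silently flips an effect sign, which is worse for
a differential analysis than losing a few percent of variants. Every input
SNP ends up exactly once in the harmonized pair or in the drop log, so
audits are lossless.

Continuous traits enter the framework through
`dichotomize_continuous()`: effects on a standardized outcome are mapped to
the case-control scale of a study whose cases are the top $q$ of the
distribution (default 20%), using the threshold-model factors
$\beta_\mathrm{bin} = \beta\,\varphi(T)/(q(1-q))$ and
$z_\mathrm{bin} = z\,\varphi(T)/\sqrt{q(1-q)}$ with $T = \Phi^{-1}(1-q)$.
This is an asymptotic approximation, validated in the test suite against a
logistic regression on a simulated cohort of $10^7$ subjects (agreement
within 5%).

## Minimal LD-score regression

`ldsc_h2()` regresses per-SNP $\chi^2$ on LD scores $\ell_j$:
$E[\chi^2_j] = \mathrm{intercept} + N h^2 \ell_j / M$. Weights
$1/[2(1 + N h^2 \ell_j/M)^2 \ell_j]$ are iterated twice from an unweighted
fit; standard errors come from a delete-a-block jackknife over
position-contiguous blocks (200 blocks by default, reduced to one block per
ten SNPs for panels under 2000). Statistics above
$\max(80,\ 0.001\,\bar N)$ are excluded before fitting, a convention that
can be disabled for simulated panels with strong single-SNP effects. A
negative fitted heritability is reported as-is with a warning rather than
truncated, so downstream summaries remain honest.

With **constant** LD scores (the "flat" mode used for simulated panels of
independent SNPs) slope and intercept are collinear. The univariate fit
then fixes the intercept at its null value 1, which makes the regression
solve exactly to $h^2 = (\overline{\chi^2}-1)M/\bar N$; the cross-trait fit
reports the weighted mean of $z_1z_2$ as the intercept and leaves genetic
covariance undefined, with a message, since the two are inseparable without
LD variation. Observed-scale estimates convert to the liability scale with
the standard transformation implemented in `liability_scale()`.

For the differential pseudo-trait we adopt the convention
$K = K_A/(K_A + K_B)$ for its "population prevalence" (the probability of
disorder A conditional on having exactly one of the two) and
$P = N_\mathrm{case}/(N_\mathrm{case}+N_\mathrm{control})$ of the
constructed contrast for the sample case fraction. This convention is what
makes the maximum-AUC computation below reproduce published values for four
disorder pairs.

## Liability-threshold prediction metrics

`liability_model(K, v)` describes a score $G \sim N(0, v)$ explaining a
fraction $v$ of a unit-variance liability, with case status assigned above
$T = \Phi^{-1}(1-K)$. All prediction metrics follow from the conditional
densities $f(g\,|\,\mathrm{case}) \propto \Phi((g-T)/\sqrt{1-v})\,\varphi(g/\sqrt v)$
and its complement:

* `max_auc()` — $P(G_\mathrm{case} > G_\mathrm{control})$ by numerical
  integration on a dense grid (20,001 points over $\pm 8.5$ score SDs,
  trapezoid rule; agreement with a closed-form normal approximation is
  within 0.005 and with a $10^7$-draw Monte-Carlo within 0.002).
* `invert_auc()` — bisection to $10^{-6}$ on the AUC, recovering $v$ from a
  published AUC.
* `risk_profile()` — absolute risk of each disorder along the score
  distribution, relative risks comparing top and bottom percentiles
  (point-percentile by default; a bin-averaged mode is provided because
  published tables do not always state which is used), variance of
  predicted risk, proportion of cases in the top $k\%$, ROC and
  predictiveness curves. In the two-disorder setting risks of the two
  disorders sum to one at every percentile.
* `ddx_prior()` — the genetics-free baseline: prior odds between the
  disorders equal to the prevalence ratio.

The numerical identity $E[\mathrm{risk}(G)] = K$ is verified to $10^{-4}$
across prevalences and variances in the test suite.

## Forecasting polygenic-score discrimination

`forecast_auc()` estimates, from the differential summary statistics alone,
the AUC a pruning-and-thresholding score would achieve on *new* patients,
for each of the 18 canonical p-value thresholds.

**Shrinkage.** Selected z-scores overstate their true effects, and a score
built from noisy weights discriminates less than its in-sample fit
suggests. `tweedie_shrink()` applies Tweedie's formula
$z_\mathrm{post} = z + \frac{d}{dz}\log\hat f(z)$, with the marginal
density $\hat f$ estimated by Lindsey's method: histogram counts on 199
bins modeled by a Poisson log-linear regression on a natural cubic spline
basis with 7 degrees of freedom (standard defaults for this estimator). A
normal-marginal fallback covers pathological fits. Because
$\sum z_\mathrm{post}^2 \approx \sum \mu z_\mathrm{post}$ for a
posterior-mean shrinker, the shrunken sum of squares estimates the
signal actually captured by the noisy weights, not the noiseless maximum —
which is what makes it the right forecasting quantity.

**From z-scores to liability units.** Each shrunken per-allele log-odds
effect $z_\mathrm{post}\,\mathrm{SE}$ is de-ascertained with the slope
$c(K_0) = \varphi(t_0)/(K_0(1-K_0))$ per liability SD, where $K_0$ is the
*population prevalence of the disorder whose study produced the effect* —
odds ratios are invariant to case-control sampling fractions, so only the
prevalence enters. A differential effect inherits the scales of its two
constituent studies; the package uses the geometric cross term
$c(K_A)c(K_B)$, exact when the prevalences are equal. Using instead the
conversion appropriate for an unascertained 50/50 study of the differential
trait would overstate the captured variance by roughly
$(c(K_0)/c(\tfrac12))^2 \approx 1.5$ at $K_0 = 0.1$ — a mistake the
end-to-end simulation check catches immediately.

**From variance to AUC.** Two mappings are provided. The default
(`mapping = "casecase"`) forecasts the contrast that is actually realized
when the score is applied to patients: both comparison groups are
ascertained beyond their own liability thresholds, and the normal
discriminant of the group difference gives
$\mathrm{AUC}_t = \Phi\!\big(\sqrt{S_t/2}\big)$ with
$S_t = \sum (z_\mathrm{post}\mathrm{SE})^2\,2p(1-p)$ the squared
per-standardized-genotype separation. `mapping = "liability"` instead
treats the de-ascertained variance as $v$ in the reduced single-liability
model of `max_auc()`. The reduced model is the right object for the
*maximum* achievable discrimination given a SNP heritability, but it
understates the separation of two tail-ascertained patient groups (a
median split of one latent variable is an easier contrast than it models);
in simulation the liability mapping runs about 0.02–0.03 below the realized
AUC while the case-case mapping tracks it to about 0.01. The liability
mapping converges, at threshold 1 with noiseless effects, exactly to
`max_auc()` of the true heritability — the consistency anchor between the
two modules — and the test suite asserts both limits.

**Effective sample size.** The default conversion is per-SNP, from the
standard error: the differential statistic's implied information is
$1/(\mathrm{SE}^2 P(1-P)\,2p(1-p))$, which automatically accounts for the
overlap correction in the SE. A scalar `n_eff` override switches to the
simpler $\hat v_t = \sum z_\mathrm{post}^2/n_\mathrm{eff}$ chain; note that
the differential SE is $\approx \sqrt{2(1-r_\mathrm{int})}$ times a
single study's SE, so a naive "total contrast size" scalar misstates the
information by about that factor squared.

`prune_snps()` implements greedy p-ordered pruning against a pairwise
$r^2$ provider (threshold 0.1, window 1000 kb by default) and passes
through unchanged when the input is declared independent, as simulated
panels are.

## The simulator

`sim_config()`/`run_validation()` implement the validation loop that
justifies the whole approach: simulate a population, run the two
overlapping case-control GWAS, form the inferred differential statistics,
and compare them against a *direct* GWAS of disorder-A-only versus
disorder-B-only patients on the same subjects.

Design, with defaults chosen to represent a realistic two-disorder setting:

* 300 independent biallelic SNPs, allele frequencies uniform on
  [0.05, 0.95]; genotypes $\mathrm{Binomial}(2, p_j)$. LD between SNPs is
  deliberately absent — the method is per-SNP, so LD affects neither its
  bias nor its calibration, only locus counting, which is out of scope.
* Liability-threshold disease model for each disorder: prevalence
  $K = 0.10$ each, liability $=$ standardized-genotype score $+$
  $N(0, 1-h^2)$, heritabilities $h^2_A = 0.2$, $h^2_B = 0.3$.
* Four SNP classes in equal parts: effects shared equally by both
  disorders, specific to A, specific to B, and null. The differential test
  is null exactly on the shared and null classes, which is what makes
  type-I error measurable alongside power.
* Per-SNP effects are drawn $\beta_j \sim N(0, h^2/n_\mathrm{causal})$
  ("random" allocation, the default). The alternative "equal" allocation
  ($\pm\sqrt{h^2/n_\mathrm{causal}}$) concentrates every causal SNP at a
  detectable effect size and drives per-SNP power toward 1 at realistic
  sample sizes; Gaussian effect sizes are the standard polygenic
  assumption and produce the graded power that real architectures show.
  For trait B, shared SNPs carry over their trait-A effects and the
  B-specific SNPs carry the remaining heritability.
* Case-control studies of $2N$ subjects each ($N$ = the larger realized
  case count): all cases plus controls free of both disorders, the two
  control sets sharing exactly $\mathrm{round}(P \cdot 2N)$ subjects.
  Per-SNP logistic regressions are exact maximum-likelihood fits computed
  from the 2×3 case/control-by-genotype contingency tables (IRLS on three
  aggregated design points, vectorized across SNPs, and verified against
  `glm()` to $10^{-7}$ in the tests).
* Without comorbidity, subjects exceeding both thresholds are alternately
  assigned to exactly one disorder; with comorbidity they keep both
  labels, and with the default shared-effect fraction about 10–20% of one
  disorder's cases also carry the other.

Validation metrics pool all SNP-by-replicate draws: correlations and RMSEs
between inferred and direct estimates, and power/type-I error at
$\alpha = 0.05$ over the differential-nonnull and differential-null classes
respectively. The problem sizes used by the package's own checks — 30
replicates at 10,000 and 20,000 expected cases for the validation table,
35 replicates of a 300-SNP fully-shared panel at 2,000 cases for null
calibration, 20 replicates with fresh 20,000-subject cohorts for the
forecasting check — are the package's chosen compromise between
Monte-Carlo error and turnaround, and are stated here so they can be
scaled up when tighter intervals are wanted.

### What the simulator does and does not emulate

It emulates overlapping control pools, comorbidity, ascertained
case-control sampling, and the prevalence/heritability regime of common
psychiatric disorders. It does **not** emulate LD (so clumping and locus
definition are untested by construction), population stratification,
covariates, imputation noise, allele-coding errors between studies, or
cross-ancestry frequency differences. Passing validation therefore shows
the estimator and its overlap correction are sound under the stated
sampling model — not that any given pair of real GWAS files is free of the
artifacts harmonization and genomic control exist to mitigate.

## Numerical choices, degenerate inputs, tie-breaks

* AUC integration: dense-grid trapezoid (20,001 points, $\pm 8.5$ SD) with
  renormalization against truncation; bisection tolerance $10^{-6}$.
* Differential variance $\le 0$ (possible only at $|r_\mathrm{int}| \ge 1$,
  which is rejected as a configuration error) yields per-SNP `NA` with a
  warning rather than a fabricated statistic; an all-degenerate pair is
  fatal.
* $\lambda < 1$ is clamped to 1; the raw value is kept in the report.
* Sorting of differential output: natural chromosome order (1–22, X, Y,
  MT), then position, then SNP ID.
* Logistic IRLS: convergence at $10^{-10}$ on the slope update, 30
  iteration cap; separation cannot occur at the simulated sample sizes and
  allele frequencies.
* `tweedie_shrink()` clamps evaluation to the fitted bin range and uses
  central differences at a tenth of the bin width for the log-density
  derivative.
* Ties in greedy pruning are broken by p-value order, then input order.

## Known limitations

* The cross-study scale factor $c(K_A)c(K_B)$ for differential effects is
  exact only for equal prevalences; for strongly discordant pairs the
  forecast inherits a first-order approximation.
* Flat-LD cross-trait fits cannot separate genetic covariance from the
  intercept; with real LD scores the separation is only as good as the
  reference panel.
* The liability model's reduction of "A versus B" to a single latent
  variable is an approximation to the underlying bivariate process; its
  known consequence for forecasting is documented above and quantified in
  the tests.
* The simulator's equal-prevalence, equal-size design mirrors the
  validation setting, not the full asymmetry of real disorder pairs.
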