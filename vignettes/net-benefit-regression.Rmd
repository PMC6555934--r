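---
title: "Net benefit regression: model, geometry and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net benefit regression: model, geometry and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbenefit)
```

## The problem

A randomised trial that collects per-patient costs $c_i$ (dollars) and
health effects $e_i$ (QALYs) supports a trial-based economic evaluation:
how much extra does the new treatment cost, how much extra health does it
buy, and is the trade worth making?  The conventional summary is the
incremental cost-effectiveness ratio
$$\mathrm{ICER} = \frac{\Delta C}{\Delta E},$$
the extra cost per extra QALY, where $\Delta C$ and $\Delta E$ are the
between-arm differences in expected cost and effect.  The ICER is awkward
statistically — it is a ratio of two correlated, noisy estimates, its
confidence interval cannot be assembled from the separate intervals of
numerator and denominator, and when the signs of $\Delta C$ and
$\Delta E$ disagree the ratio is a meaningless negative number.

Net benefit regression recasts the whole analysis as ordinary least
squares.  For a willingness-to-pay (WTP) threshold $\lambda$ (dollars per
QALY), each patient's net benefit is
$$NB_i(\lambda) = \lambda\, e_i - c_i,$$
and the regression
$$NB_i = b_0 + b_{TX}\,TX_i + b_1 X_{1i} + \cdots + b_p X_{pi} + \varepsilon_i$$
on the binary treatment indicator $TX$ makes $b_{TX}$ the incremental net
benefit $INB(\lambda) = \lambda \Delta E - \Delta C$, with an honest OLS
confidence interval.  Because the NB outcome mixes cost and effect inside
one residual, the interval automatically carries the within-patient
cost-effect correlation that separate cost and effect intervals ignore.

## Model and assumptions

* **Estimation.**  All fits are classical OLS with homoskedastic standard
  errors and $t$-based two-sided p-values on $n - p - 1$ residual degrees
  of freedom.  A heteroskedasticity-consistent (HC1) option exists but is
  off by default, keeping the default inferential machinery the plain one.
  We use the $t$ rather than the normal reference throughout; at trial
  sizes of 150+ per analysis the difference is negligible, but it is a
  documented choice.
* **Shared design.**  The cost, effect and NB regressions in one analysis
  always share one covariate list and hence one design matrix.  This
  preserves the exact identities below and is what makes the residual
  cross-covariance $s_{EC} = \sum_i r_{E,i}\, r_{C,i} / df$ well defined.
* **Complete cases.**  Rows with missing cost or effect are rejected with
  an error, never silently dropped or imputed: a silent drop changes the
  arms' composition and biases $\Delta C$ and $\Delta E$.  Negative costs
  are rejected by default (an override exists for genuine credits).
* **Randomised comparison.**  Covariates are for precision and subgroup
  exploration; nothing here corrects for confounding in non-randomised
  data.

### Exact identities the implementation maintains

These hold to numerical precision and are enforced by the test suite:

1. $b_{NB}(\lambda) = \lambda\, b_E - b_C$ coefficient by coefficient,
   for any shared covariate set.
2. $INB(0) = -\Delta C$; the INB-by-WTP line has slope $\Delta E$ and
   x-intercept $\Delta C / \Delta E$ (the ICER) when $\Delta E > 0$.
3. Residual-variance composition:
   $s^2_{NB}(\lambda) = \lambda^2 s^2_E - 2\lambda\, s_{EC} + s^2_C$.
   This is how the NB regression "knows" the cost-effect correlation.
4. With no extra covariates, treatment coefficients equal arm-mean
   differences exactly, and the saturated interaction model reproduces the
   stratified point estimates exactly (standard errors legitimately differ:
   pooled versus stratum residual variance).

## WTP sweeps, Fieller limits, quadrant policy

The WTP is a decision-maker's parameter, not an estimable quantity, so it
is swept: the default grid is \$0 to \$500,000 in \$50,000 steps, fully
configurable.  The grid serves only tabulation and plotting.  Every
derived crossing is computed from the closed-form line
$\lambda \Delta E - \Delta C$ and the closed-form SE function
$SE(\lambda) = \sqrt{\lambda^2 v_E - 2\lambda\, c_{EC} + v_C}$
(coefficient-scale variances), never by grid interpolation — Fieller
limits must not depend on grid spacing.

The WTP values where the INB confidence bounds cross zero are the Fieller
confidence limits for the ICER.  `fieller_ci()` solves
$INB(\lambda) \pm t_{crit} SE(\lambda) = 0$ with a safeguarded scalar
root-finder: each bound function is scanned on an expanding bracket
(growing by two orders of magnitude per round, eight rounds, so crossings
out to $\sim 10^{15}$ are found) and polished with `uniroot()` to a
relative tolerance that leaves $|INB|/SE$ within $10^{-6}$ of $t_{crit}$
at any returned limit.  A bound that never crosses for $\lambda \ge 0$
yields an unbounded (`Inf`) limit — the correct Fieller answer when
$\Delta E$ is not significantly positive — and the search domain excludes
negative WTP, which has no decision meaning.  When every SE is zero the
limits collapse to the point ICER.

**Quadrant policy.**  The ICER is reported only when its sign is
interpretable: costlier-and-more-effective (trade-off) or
cheaper-and-less-effective.  In the mixed-sign quadrants (dominant,
dominated) the ratio is suppressed and the quadrant label returned; the
INB, which is well defined in every quadrant, carries the result instead.
Displayed ratios are rounded to the nearest whole dollar (the policy that
reproduces published whole-dollar ICERs from their underlying estimates);
full precision is retained internally.

## Acceptability curves and the bootstrap

The parametric CEAC converts the NB regression's two-sided p-value $p_2$
at each grid point to the one-sided probability that the treatment is
cost-effective: $1 - p_2/2$ when the INB estimate is positive, $p_2/2$
when negative, exactly $0.5$ at zero.  The conversion rule is stated
prominently because published applications often cite it without
restating it.  Consequences worth knowing: the curve passes through 0.5
at the point-estimate ICER; at $\lambda = 0$ it is the one-sided
probability that the treatment saves money; as $\lambda \to \infty$ it
tends to the one-sided probability that $\Delta E > 0$ — *not* to 0 or 1.

The nonparametric alternative resamples patients with replacement
**within arm**, preserving the randomised arm sizes (the resampling unit
is the patient; stratification by arm respects the design).  Replicate
increments come from arm-mean differences (unadjusted) or full refits
(adjusted).  Degenerate zero-variance replicates are retained and
flagged, never redrawn, so the resampling distribution is untouched.
Bootstrap CEACs count replicates with positive INB, exact zeros counting
one half.  Intervals are percentile intervals — the simplest defensible
choice, adequate for the near-symmetric INB distributions at trial-scale
$n$; BCa is a possible extension, not implemented.  All randomness runs
under an explicit integer seed with a named generator
(Mersenne-Twister / Inversion / Rejection) in a scoped RNG state, so
results are bit-reproducible and the caller's RNG stream is untouched.

## Subgroups

`interaction_fit()` adds a subgroup main effect and a
treatment-by-subgroup interaction to the NB regression: the `tx`
coefficient is the reference-level INB, the interaction is the INB
difference between levels, and their sum is the other level's INB with a
delta-method SE from the full coefficient covariance
($\mathrm{Var}(b_{TX}) + \mathrm{Var}(b_{TX \times G}) + 2\,\mathrm{Cov}$
— exact under OLS).  `stratified_analysis()` runs independent sweeps per
stratum; with no extra covariates the two routes agree exactly on point
estimates.  For a subgroup defined by a continuous variable,
stratification would force an arbitrary cut; the same interaction design
with $TX \times x$ reports the INB at user-chosen moderator values
instead.  No multiplicity correction is applied across subgroups: these
are hypothesis-generating explorations, and the output says so rather
than lending them confirmatory weight.

## The synthetic-trial generator

Real person-level cost-effectiveness datasets are rarely shareable, so
the package carries a generator with known truths;
`co17_like_preset()` encodes the study conditions used throughout the
package's validation: a two-stratum biomarker trial (150 mutant-like and
216 wild-type-like patients, split equally across arms) with stratum
incremental costs \$13,787 and \$30,843 and incremental effects
$-0.0172$ and $0.1769$ QALYs — one stratum in the dominated quadrant,
one in the trade-off quadrant with an ICER near \$174,000/QALY.

Choices behind the preset's remaining constants, which published
incremental tables do not determine:

* **Control-arm baselines** (\$15,000 cost; 0.35 / 0.40 QALYs) are
  plausible magnitudes for supportive care of advanced cancer over
  roughly 18 months; they are documented constants, not estimates of any
  trial, and only the increments drive validation.
* **Effect SDs** (0.13 and 0.27 QALYs) were back-calculated once from the
  printed significance of the stratum incremental effects (a p-value of
  0.42 at $n = 150$ and $p < 0.001$ at $n = 216$ imply those scales).
* **Costs are lognormal with unit coefficient of variation** — strongly
  right-skewed (skewness $\approx 4$), as trial cost data typically are;
  gamma and normal families are available.  The lognormal and gamma draws
  are mean-preserving, so configured arm means are exact in expectation.
* **Cost-effect correlation** $\rho = 0.3$ (sicker patients accrue more
  cost and fewer QALYs in a correlated way) is induced through a shared
  latent standard-normal factor; $\rho$ is exact on the latent scale and
  approximate on the observed scale for the skewed families.

What the generator does **not** emulate: censored follow-up and
administrative truncation (no survival times are generated at all),
utility-instrument structure in the QALYs, covariate-driven cost
heterogeneity unless explicitly configured, and multi-centre or
non-randomised structure.  Tests passing on these synthetic trials
therefore validate the estimators' algebra, calibration and coverage
under clean randomisation with skewed costs — they do not validate
censoring corrections, which are explicitly out of scope.

## Numerical choices

* OLS solves go through a QR decomposition, not the normal equations;
  rank deficiency is detected at R's machine-epsilon-scaled tolerance and
  reported with the names of the collinear columns.
* Zero residual variance (degenerate outcomes) is handled explicitly:
  SE 0, p-value 0 for a nonzero coefficient and 1 for a zero one.
* Bootstrap ties at INB exactly 0 count one half (symmetry; measure zero
  under continuous data).
* Display rounding: whole dollars, 4-decimal QALYs and p-values; all
  machine-readable outputs carry full precision, and dataset CSVs are
  written with 17 significant digits so round trips are exact.
* Categorical covariates are dummy-coded against a first-appearance
  reference level, fixed at dataset construction, so adjusted fits are
  reproducible regardless of row order downstream.

## Validation problem sizes

The shipped tests exercise: exact identities on small random trials;
Fieller limits against the closed-form quadratic on bivariate-normal
trials of 400/arm; parameter recovery and 95% INB interval coverage over
200 replicated generations of the preset scaled to 2000 patients per arm
per stratum (coverage checked at $\lambda$ = \$100,000); and
bootstrap-versus-parametric CEAC agreement (sup-norm $\le 0.03$) on a
bivariate-normal trial of 500/arm with 5000 seeded replicates.  These
sizes give Monte-Carlo error comfortably below the tolerances being
asserted while keeping the whole suite under a minute.

## Known limitations

* No censoring-aware cost or effect estimation; inputs are assumed
  complete over the analysis horizon.
* No GLM families for skewed costs (gamma log-link etc.); OLS on the
  dollar scale only, which is the estimand-faithful choice for means but
  can be inefficient under heavy skew.
* Fieller limits are reported on $[0, \infty]$ only; a negative-WTP
  branch has no decision-analytic meaning here.
* The whole-sample INB of a mixed population is the prevalence-weighted
  average of stratum INBs only when covariate sets are shared; reporting
  focuses on strata when interactions are material.
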