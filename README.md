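# netbenefit

Net benefit regression for trial-based cost-effectiveness analysis in R.

Health-economic analysts evaluating a randomised trial that collected
per-patient costs and QALYs face three recurring problems: the incremental
cost-effectiveness ratio (ICER = ΔC/ΔE) is a ratio of correlated noisy
estimates whose confidence interval cannot be built from the separate ΔC and
ΔE intervals; the "right" willingness to pay (WTP) for a QALY is unknown; and
when ΔC and ΔE have opposite signs the ICER is a meaningless negative number.
`netbenefit` addresses all three by putting the analysis in a regression
framework.  Each patient's net benefit at WTP λ is

    NB_i(λ) = λ · e_i − c_i

and OLS of NB on a binary treatment indicator TX gives the incremental net
benefit as the treatment coefficient:

    INB(λ) = λ·ΔE − ΔC,

with an honest confidence interval (the NB residual carries the cost–effect
correlation: s²_NB(λ) = λ²s²_E − 2λ·s_EC + s²_C).  Swept across λ, the INB
traces a line with y-intercept −ΔC, slope ΔE and x-intercept the ICER; the
WTP values where its confidence bounds cross zero are the Fieller confidence
limits for the ICER, and the one-sided p-values give the cost-effectiveness
acceptability curve (CEAC).  Covariate adjustment, treatment-by-subgroup
interactions and stratified analyses are ordinary regression moves.

The package provides:

- `ce_dataset()` / `read_ce_csv()` — validated person-level container and
  strict delimited-text I/O;
- `fit_cost()`, `fit_effect()`, `fit_nb()` — the three OLS regressions on TX;
- `incremental_summary()`, `icer()` — ΔC, ΔE with the residual
  cross-covariance, and the ICER with a dominance-quadrant policy (mixed-sign
  ratios suppressed);
- `sweep_inb()`, `fieller_ci()`, `extrapolate_inb()` — the INB-by-WTP curve,
  Fieller ICER limits by root-finding on the closed-form line, and linear WTP
  extrapolation;
- `ceac_parametric()`, `bootstrap_replicates()`, `ceac_bootstrap()`,
  `bootstrap_ci_inb()` — parametric and seeded arm-stratified bootstrap
  uncertainty;
- `interaction_fit()`, `stratified_analysis()` — subgroup machinery;
- `synth_config()`, `generate_ce_trial()`, `co17_like_preset()` — a seeded
  synthetic-trial generator with known incremental truths;
- `analyze_ce()`, `simulate_ce()` and a thin command-line wrapper
  (`inst/cli/nbr`) that writes the full result bundle (summary tables, INB
  curves, CEACs, interaction table, JSON manifest).

## Worked example

A synthetic two-stratum biomarker trial (366 patients; a mutant-like stratum
where the new treatment is costlier and slightly less effective, and a
wild-type-like stratum where it is costlier but clearly more effective):

```r
library(netbenefit)

ds <- generate_ce_trial(co17_like_preset(seed = 42))
strata <- stratified_analysis(ds, "subgroup", default_wtp_grid())

strata$WT$summary
#> Incremental cost   :     24869.09 (SE 3524.01, p = 2.331e-11)
#> Incremental effect :       0.1761 (SE 0.0355, p = 1.442e-06)
#> n = 216, residual df = 214, coef covariance = 45.47

icer(strata$WT$summary)
#> 141,213 $/QALY (trade-off)

strata$WT$ci_crossings
#> $lower
#> [1] 97163.12
#> $upper
#> [1] 224729.9

icer(strata$MUT$summary)
#> ICER suppressed: dominated (new treatment costs more and is less effective)
```

Reading: in the wild-type-like stratum the treatment buys 0.176 extra QALYs
for $24,869 extra cost — $141,213 per QALY, with a Fieller 95% interval of
roughly $97k–$225k (the WTP range over which the INB confidence bounds
straddle zero).  In the mutant-like stratum the estimate sits in the
dominated quadrant, so no ratio is printed; its INB is negative at every WTP
on the grid, which is the interpretable statement.  Because the INB is
linear in WTP, a published INB at one threshold determines it at any other:

```r
extrapolate_inb(inb_ref = -13154, wtp_ref = 1e5, wtp_new = 123456,
                delta_effect = 0.1769)
#> [1] -9005
```

The same analysis from a shell, given a CSV with `tx`, `cost`, `effect`
columns:

```sh
inst/cli/nbr simulate --out trial.csv --seed 42
inst/cli/nbr analyze --input trial.csv --out results/ --subgroup subgroup
```

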