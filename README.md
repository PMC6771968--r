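# necsuff

Degrees of necessity and sufficiency for binary and survival outcomes.

## The problem

Clinical and epidemiological studies usually summarize a prognostic factor
by an odds ratio, a hazard ratio or a p-value. None of these answers two
questions that sit at the heart of causal thinking:

- How *necessary* is the factor — can the outcome develop without it?
- How *sufficient* is it — is the outcome unavoidable in its presence?

`necsuff` quantifies both on a 0–1 scale. For an event *D* and factor *X*,
the protective range of *X* is where P(*D* | *X*) < P(*D*) and the harmful
range where it is above. The degree of necessity and of sufficiency are

    DN1 = sqrt( E[ ((P(D) - P(D|X)) / P(D))^2      | X protective ] )
    DS1 = sqrt( E[ ((P(D|X) - P(D)) / (1 - P(D)))^2 | X harmful    ] )

with second variants DN2, DS2 that average the kernels without squaring
(so DN1² ≤ DN2 ≤ DN1 always). DN generalizes the attributable risk, DS
the reverse attributable risk, and together they decompose explained
variation: EV = DN·DS exactly for a 2×2 table, and

    EV = (1-α)·odds(D)·DN1² + α·odds(¬D)·DS1²

in general, where α = P(X harmful). For right-censored survival data the
same kernels compare conditional and unconditional cumulative incidence at
every distinct event time and are averaged with inverse-probability-of-
censoring (reverse Kaplan–Meier) weights, making the estimates consistent
under random censoring and invariant to monotone time transformations.

The measures need only unconditional and conditional outcome probabilities
— from logistic or Cox regression, parametric models, or any calibrated
prediction tool. The package is aimed at biostatisticians and
epidemiologists who want to report *why* an explained-variation value is
large or small: because the factor is necessary, sufficient, or both.

## What is in the package

- `dn_ds()` — one generic for probability vectors, `two_by_two()` tables
  and `survival_curves()` objects (built by `cox_curves()` from a Cox fit
  or stratified Kaplan–Meier, or from any user-supplied incidence matrix).
- `boot_dn_ds()` — percentile and BCa bootstrap intervals that refit the
  model per replicate and apply a direction-consistency truncation rule.
- `pop_2x2()`, `pop_logistic_normal()`, `pop_survival()` — exact and
  quadrature-based population values for two-point, logistic-normal and
  two-group exponential scenarios.
- `gen_logistic_normal()`, `gen_2x2()`, `gen_exp_survival()`,
  `simulation_study()` — seeded generators and a bias/coverage harness.
- `run_cli()` plus the `inst/exec/necsuff` script for shell use.

## Worked example

A 33-year Swedish cohort of 12,664 males cross-classifies smoking with
death from lung cancer (8120 / 4331 never/ever smokers alive or dead from
other causes, 36 / 177 lung-cancer deaths):

```r
library(necsuff)
tab <- lung_cancer_table()
dn_ds(tab)
#> Degrees of necessity and sufficiency
#>   protective level: X = 0
#>   DN1   DN2   DS1   DS2    EV
#> 0.738 0.738 0.023 0.023 0.017
#> baseline P(D) = 0.017, alpha = 0.356, n< = 8156, n> = 4508, n = 12664
relative_risk(tab)
#> [1] 8.895371
```

Although smoking raises the risk of lung-cancer death almost nine-fold, it
explains under 2% of outcome variation. The decomposition shows why:
smoking is highly *necessary* (DN = 0.74 — most deaths occurred among
smokers) but barely *sufficient* (DS = 0.02 — most smokers did not die of
lung cancer), and with a rare outcome (P(D) = 1.7%) EV is dominated by the
sufficiency term.

The same analysis from the shell:

```sh
inst/exec/necsuff twobytwo --counts 8120,4331,36,177
```

For survival data:

```r
d <- gen_exp_survival(5000, hr = 10, alpha = 0.5,
                      censoring = "administrative", tau = 4.9, seed = 1)
dn_ds_surv(d$time, d$status, d$group, method = "km", tau = 4.9)
#> Degrees of necessity and sufficiency
#>   DN1   DN2   DS1   DS2    EV
#> 0.675 0.675 0.435 0.435 0.326
#> baseline P(D) = NA, alpha = 0.487, n< = 2564, n> = 2436, n = 5000
```

which at large n converges to the population values
`pop_survival(10, 0.5, tau = 4.9)` (DN = 0.711, DS = 0.438, EV = 0.340).

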