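---
title: "Quantifying necessity and sufficiency of prognostic factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying necessity and sufficiency of prognostic factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necsuff)
```

## The model

A condition is necessary for an event if the event cannot develop without
it, and sufficient if the event is unavoidable in its presence. `necsuff`
measures both *degrees* for a prognostic factor $X$ and event $D$ with
$0 < P(D) < 1$. Levels of $X$ with $P(D \mid X) < P(D)$ are called
*protective*, levels with $P(D \mid X) > P(D)$ *harmful*; ties are
noninformative and contribute to neither side. The degree of necessity is

$$DN_1 = \sqrt{E_{X<}\left[\left(\frac{P(D) - P(D \mid X)}{P(D) - 0}\right)^2\right]},
\qquad
DN_2 = E_{X<}\left[\frac{P(D) - P(D \mid X)}{P(D) - 0}\right],$$

where $E_{X<}$ conditions on the protective range. The explicit $-\,0$
emphasizes the normalization: the observed drop of the conditional below
the unconditional probability is standardized to the maximal hypothetical
drop, to $P(D \mid X) = 0$. Symmetrically, the degree of sufficiency
normalizes the rise of $P(D \mid X)$ above $P(D)$ by the distance to 1:

$$DS_1 = \sqrt{E_{X>}\left[\left(\frac{P(D \mid X) - P(D)}{1 - P(D)}\right)^2\right]},
\qquad
DS_2 = E_{X>}\left[\frac{P(D \mid X) - P(D)}{1 - P(D)}\right].$$

Both measures live in $[0,1]$. $DN = 1$ exactly when no event occurs at
any protective level; $DS = 1$ exactly when the event is certain at every
harmful level. Jensen's inequality gives $DN_2 \le DN_1$, and because the
kernels are bounded by 1, $DN_2 \ge DN_1^2$ (likewise for $DS$). The
variant-1 forms square the kernels before averaging and therefore weight
extreme conditional probabilities more heavily; the square root returns
the result to the probability scale. We default to reporting both.

For a dichotomous factor the $DN$ kernel is the attributable risk
$AR = (P(D) - P(D \mid X{=}0))/P(D)$, the relative reduction in event
probability were everyone shifted to the unexposed level, and the $DS$
kernel is the reverse attributable risk
$AR^* = (P(\neg D) - P(\neg D \mid X{=}1))/P(\neg D)$. `dn_ds()` applied
to a `two_by_two()` table uses the closed forms: with cross product
$ad - bc > 0$,

$$\widehat{DN} = \frac{ad-bc}{(a+c)(c+d)}, \qquad
\widehat{DS} = \frac{ad-bc}{(a+b)(b+d)}, \qquad
\widehat{EV} = \frac{(ad-bc)^2}{(a+b)(a+c)(b+d)(c+d)},$$

with the roles of the columns exchanged when $ad - bc < 0$ (the
`protective_level` component records the resolution). Here
$EV = DN \cdot DS$ holds exactly, and all three are invariant under
inverting the odds ratio.

## Explained variation and its decomposition

$EV$ is the relative reduction in predictive inaccuracy when conditional
predictions replace the unconditional one,
$EV = 1 - E_X[P(D|X)(1-P(D|X))] / [P(D)(1-P(D))]$. When the predictions
are calibrated ($E_X P(D\mid X) = P(D)$) this equals the squared-deviation
form $E_X[(P(D|X)-P(D))^2]/[P(D)(1-P(D))]$, which splits over the
protective and harmful ranges into

$$EV = (1-\alpha)\,\frac{P(D)}{1-P(D)}\,DN_1^2
     + \alpha\,\frac{1-P(D)}{P(D)}\,DS_1^2,$$

with $\alpha = P_X(P(D \mid X) > P(D))$ the probability of a harmful
level (`ev_decomposition()`). The weights explain a recurring empirical
pattern: for rare outcomes $EV$ is driven almost entirely by sufficiency,
so a factor can be almost perfectly necessary and still explain next to
nothing. For $DN_2, DS_2$ no exact decomposition exists, but
$EV \ge DN_2 \cdot DS_2$ always holds under calibration, and
$DN_1 \cdot DS_1$ is typically close to $EV$.

`dn_ds()` defaults to the plug-in ("indirect") estimator of $EV$ and
offers the squared-deviation form via `ev = "deviation"`; the two differ
only for miscalibrated inputs, and the choice is recorded in the result.
The default baseline $\bar p$ is the outcome mean when outcomes are
supplied (the model-free choice, equal to the prediction mean for
calibrated models) and the prediction mean otherwise.

## Survival outcomes

With right-censored data the comparison is between conditional and
unconditional cumulative incidence, $F(t \mid X)$ versus $F(t)$. At any
fixed $t$ the situation is the dichotomous one; averaging the per-time
measures over the event density on a horizon $[0, \tau]$ gives
$DN_1(\tau)$ and $DS_1(\tau)$. The sample estimator evaluates the kernels
at each distinct event time $t_{(j)}$ — $F$ from the Kaplan–Meier
estimator, $F(\cdot \mid x_i)$ from Cox regression
(`cox_curves(method = "cox")`, Breslow baseline), stratified Kaplan–Meier
(`method = "km"`), or any external matrix of conditional incidences
(`survival_curves()`) — and forms the weighted average

$$\widehat{DN}_1 = w^{-1} \sum_j \hat G(t_{(j)}{-})^{-1} d_j\, \widehat{DN}_{1,t_{(j)}},
\qquad w = \sum_j \hat G(t_{(j)}{-})^{-1} d_j,$$

where $\hat G$ is the Kaplan–Meier estimator of the censoring
("potential follow-up") distribution, obtained by reversing the event
indicator. The $\hat G^{-1}$ weights compensate the depletion of observed
late events by earlier censoring, which is what keeps the estimates
stable under random censoring before $\tau$ while still — deliberately —
depending on $\tau$ itself. Everything is rank-based, so any strictly
increasing transformation of the time scale leaves the output bit-identical.
For a dichotomous factor the two variants coincide at every time and
overall.

The accompanying explained variation (`sh_ev()`) is the
Schemper–Henderson measure: at each event time a subject still under
observation contributes absolute inaccuracy $1 - S(t)$, a subject known
dead contributes $S(t)$, and a subject censored earlier at $t_i$
contributes the expectation
$(S(t)/S(t_i))(1 - S(t)) + (1 - S(t)/S(t_i))S(t)$, splitting on its
probability of still being alive; $EV$ is one minus the ratio of the
weighted conditional to unconditional mean inaccuracies.

## Numerical and design choices

Several points are underdetermined by the definitions; the package
resolves them as follows.

- **Reverse-KM ties and side.** $\hat G$ is evaluated as its left limit
  at each event time, so a weight never conditions on censorings tied to
  that time and all weights are finite and $\ge 1$. Beyond the last
  censoring the last positive value is carried forward.
- **Empty informative sets.** If no subject is on the protective
  (harmful) side at some event time, that time is dropped from numerator
  *and* denominator of the affected measure — the conditional-expectation
  reading — rather than diluted in as a zero. `drop_empty = FALSE`
  switches to the diluting convention. For a whole sample with an empty
  side, the measure is 0.
- **Ties at the baseline.** Strict inequalities define the informative
  sets; `tol` (default 0) widens the tie region for noisy predictions.
- **Horizon.** $\tau$ defaults to the largest observation time and the
  package never extrapolates beyond it; a $\tau$-free variant would
  implicitly extrapolate the model past the data and is out of scope.
- **Negative values.** Sample $EV$ for survival can be negative; it is
  clipped to 0 with a flag. Partial measures (differences between nested
  models, `partial_measures()`) can legitimately be negative and are
  returned unchanged with a warning. Point estimates are never truncated
  toward 0 outside the bootstrap rule below.
- **Quadrature and root-finding.** Population calculators use
  `stats::integrate` (absolute tolerance `1e-8` or tighter) and
  `stats::uniroot` to `1e-10`. The survival kernels are rewritten in
  survival-function form (`expm1`-based) to stay finite in the far tail;
  infinite horizons integrate directly over $(0, \infty)$. Structural
  odds ratios of $0$ or $\infty$ are handled as exact zero-cell tables,
  not numerical limits.
- **Survival population orientation.** In the two-group exponential
  family the harmful level has hazard 1 and the protective level hazard
  $1/HR$. This orientation is the one that reproduces the censoring
  fractions of the package's follow-up designs (31% type-I censoring at
  $HR = 10$, $\tau = 4.90$; 43% at $HR = 100$, $\tau = 15.30$).

## Bootstrap intervals

`boot_dn_ds()` resamples whole observation rows and reruns the full
model fit per replicate (`B = 1000` and BCa by default). Because the
protective/harmful labelling could flip in a replicate and silently turn
a near-null $DN$ into a large one, the partition is frozen from the
original sample, and a replicate whose mean prediction over the original
harmful range falls below that over the protective range has its
measures set to 0. $EV$ is truncated exactly when $DN$ and $DS$ are —
the rule fires jointly, which is the coherent reading for a product-like
decomposition. For survival fits the rule compares reverse-KM-weighted
average conditional incidences over the frozen subject sets, the direct
analogue on the incidence scale. BCa bias-correction uses the fraction
of replicates below the point estimate (ties split) and a one-pass
jackknife for the acceleration of all measures; degenerate corrections
fall back to the percentile interval.

## What the simulations emulate — and what they do not

`gen_logistic_normal()` (standard-normal factor, logistic outcome),
`gen_2x2()` (multinomial draws from solved cell probabilities) and
`gen_exp_survival()` (two-group exponential with none / type-I /
administrative-uniform censoring) generate exactly the families for which
the population calculators provide truth, so `simulation_study()` can
report genuine bias, coverage and width. The defaults mirror the
validation conditions: 250 replicates for bias studies, $n = 200$ and
$500$, nominal 95% intervals.

These families are deliberately idealized: proportional hazards holds
exactly, censoring is noninformative by construction, covariates are
clean and complete. Passing tests therefore demonstrate correctness of
the estimators and calculators under the stated models — not robustness
to informative censoring, model misspecification or measurement error in
real data. Estimation also assumes outcome-representative sampling;
case-control data would need external baseline information.

Problem sizes in the test suite were chosen to make Monte-Carlo error
small relative to the assertion tolerances: consistency checks use
$n = 10^5$ (tolerance $\pm 0.02$), Monte-Carlo cross-checks of the
quadrature use $10^6$ draws ($\pm 0.005$), and the coverage study uses
200 datasets of $n = 200$ with 200 BCa replicates each, whose binomial
error of about $\pm 1.6$ percentage points sits comfortably inside the
asserted band.

## Known limitations

- No competing risks, left truncation or time-dependent covariates.
- Small-sample estimates of measures whose population value is 0 are
  biased upward (they cannot be negative); under heavy censoring this
  bias grows, which is why interval estimates are recommended alongside
  points.
- The population calculators cover two-point and standard-normal factor
  distributions; other distributions are served by large-$n$ simulation
  through the estimators.

## A worked call

```{r example}
tab <- lung_cancer_table()
dn_ds(tab)
ev_decomposition(dn1 = 0.738, ds1 = 0.023, alpha = 0.356, p_bar = 0.017)
```
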