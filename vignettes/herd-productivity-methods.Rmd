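---
title: "Methods: simulating, modelling and optimizing dairy-herd productivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, modelling and optimizing dairy-herd productivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdopt)
```

## The problem

Daily milk yield in a commercial dairy herd responds to ration
composition, parity, stage of lactation and gestation, age and ambient
temperature — and so does the feed required to produce it. `herdopt`
implements a complete workflow around a main-effects linear model of six
such factors and two responses (milk yield in L/24 h, dry-matter intake
in units/cow): simulate cow-day records with realistic marginals,
summarise them, fit and test the two regressions, and then find the
factor settings that best trade higher predicted milk against lower
predicted intake inside agronomic box constraints.

The package ships a *reference calibration*: marginal moments, bounds and
skewness for the six factors and two responses, and the two fitted
equations, corresponding to a two-year record set of 17 500 cow-day
observations from a large-scale Holstein operation. All defaults derive
from it; every piece is overridable.

## The synthetic herd generator

Real herd records are rarely shareable, so the generator is a
first-class module, not a test fixture. Each factor gets a distribution
family chosen for the shape its marginal actually has:

* **Truncated skew-normal** (TMR dry-matter %, day of lactation, age,
  temperature). A skew-normal with location, scale and slant is
  truncated to the factor's observed `[lower, upper]`; the three
  parameters are solved by root-finding so that the *truncated* mean and
  SD equal the targets exactly (numerical quadrature of the truncated
  moments inside a Nelder–Mead solve, warm-started across the outer
  1-d search over the slant). Skewness is matched as closely as the
  family allows: with bounds two or more SDs from the mean the
  attainable skewness is bounded (roughly below 1 in magnitude), so
  targets such as 1.25 for age are approached, not hit. The spec is
  rejected with a named calibration error when no member of the family
  can reach the requested mean/SD inside the bounds (for example an SD
  wider than the support allows).
* **Truncated geometric** (lactation number). Parity is an integer count
  on 1–8 whose reported dispersion and quartiles are not internally
  consistent with that range, so only the mean (2.252) and the range are
  trusted; a geometric distribution truncated to {1, …, 8} with success
  probability solved from the mean reproduces the strong concentration
  at low parities.
* **Truncated exponential** (gestation day). A first quartile at the
  lower bound signals strong right concentration near small values; an
  exponential truncated to [1, 230] with rate solved from the mean
  (66.454) captures it with one parameter.

Sampling is inverse-CDF throughout (numeric CDF on a 4001-point grid for
the skew-normal; closed forms otherwise), which makes generation
deterministic given the seed and lets an optional Gaussian copula impose
a factor correlation matrix on the ranks without disturbing any
marginal. Factors are independent by default because the reference
calibration reports no covariances.

Responses are linear in the factors plus homoscedastic Gaussian noise,
consistent with the OLS error model that is fitted downstream. Two
calibrations connect the equations to the reported response marginals:

1. **Variance.** `implied_residual_sd()` sets the noise SD to
   `sqrt(target_variance - var(X beta))`, floored at
   `1e-6 * target_variance`, so the simulated response's marginal
   variance lands on its target (80.979 L² for milk, 7.705 for intake).
2. **Mean.** The reference milk equation evaluated at the factor means
   reproduces the reported milk mean almost exactly (51.86 vs 51.856),
   but the intake equation evaluates to 27.97 against a reported
   marginal mean of 24.233 — the printed intercept and the printed
   marginal cannot both hold. The generator therefore accepts optional
   response target means and applies a deterministic intercept offset,
   `target_mean - (b0 + sum(b_j * mean_j))`, leaving all slopes
   untouched. Slope-recovery properties are unaffected; only the level
   of the simulated intake series is anchored to the reported marginal.

What the generator does *not* emulate: per-cow longitudinal structure
(rows are exchangeable cow-days, not trajectories), seasonal temperature
paths, heat-stress indices, and any factor–factor dependence beyond the
optional copula. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated marginal and linear structure,
not fidelity to every feature of real herd data — in particular the
simulated milk marginal is close to symmetric, while real yield
distributions are mildly left-skewed.

Default herd size is 17 500 records. Tests exercise the machinery at
n = 2 000 (and the calibration checks once at full size), sizes at which
every sampling distribution involved is already well inside its
asymptotic regime.

## Descriptive conventions

Printed descriptive panels differ across software mostly in three
conventions, all fixed here so ports agree digit-for-digit:

* quartiles by the `(n+1)p` position rule with linear interpolation,
  clamped to `[1, n]` (R's `quantile(type = 6)`);
* skewness as the adjusted Fisher–Pearson statistic
  `g1 * sqrt(n(n-1))/(n-2)`;
* kurtosis as excess kurtosis with the standard small-sample adjustment,
  so large normal samples read 0.

Statistics that a degenerate group cannot support (dispersion with one
row, skewness with two) surface as explicit `NA` markers, never as
silent zeros. Grouped panels use contiguous half-open bins `[a, b)` with
the last bin closed; the default age grouping is
`22.3, 42.4, 62.4, 82.4, 102.4, 110` months.

## Regression and intervals

`fit_ols()` solves by QR decomposition (no normal-equation inversion),
errors on rank deficiency naming the collinear columns, and warns above
condition number 1e8. The default model is main effects only — the
reference equations carry no products — with pairwise interactions
behind a flag.

The ANOVA is *adjusted* (Type III): each term's SS is the increase in
residual SS when that term alone is removed, obtained by literal
reduced-model refits, so the identity `F = t^2` for 1-df terms is an
emergent property rather than a construction. Continuous predictors
carry 1 df. Exact p-values are stored; `format_anova()` floors the
displayed values at 0.001, matching the classical print style.

Intervals at a design point `x0` use the textbook formulas: CI
`fit ± t * se_fit` with `se_fit = sqrt(x0' Cov x0)` and PI
`fit ± t * sqrt(s^2 + se_fit^2)`, `t` on the residual df. The CI is
strictly inside the PI whenever `s^2 > 0`, and as n grows the PI
half-width tends to `t * s` — both are asserted as properties in the
test suite.

## The optimization model

The bi-objective program — maximize predicted milk, minimize predicted
intake over a box — needs a scalarization to have a well-defined
solution; conflicting linear objectives have no interior compromise
otherwise. The package adopts the Derringer–Suich composite
desirability, the de facto standard for multi-response optimization of
fitted response surfaces: each prediction maps to `[0, 1]` through a
one-sided power ramp between two anchors, and the composite `D` is the
importance-weighted geometric mean. Defaults are weight 1 (linear
ramps) and equal importances; anchors default to each response's
observed range (milk 24.5–70.4 L, intake 14.51–34.4 units), so a
desirability of 1 means "as good as the best value ever observed".

Box defaults: TMR dry matter 46.77–56.49 %, lactation number 1–8
(integer), lactation day 6–350, gestation day 1–230, age 22.3–110
months, temperature 2.2–38.8 °C. The TMR lower bound is set to the
observed minimum 46.77 % — the value the reference optimum itself sits
on — rather than a looser bound, and every bound is overridable in the
problem constructor and the pipeline config.

The solver is a projected compass (pattern) search: derivative-free
because `D` has kinks wherever a prediction crosses an anchor, bounded
by projection so coordinate steps land exactly on the bounds (which is
why monotone objectives finish *exactly* at vertices), and monotone in
`D` by construction. It is restarted from every vertex of the box's
2-level design plus `n_starts` seeded uniform interior points; step
halving stops at 1e-10 of each factor's range. Integer factors are
relaxed during the search and finished by exhaustive comparison of the
neighbouring lattice points. Equal-`D` terminal points are resolved by
distance to the box centre, then start order, so results are
reproducible. `grid_oracle()` — exhaustive evaluation on a regular grid,
first point wins ties in row-major order — is the independent
verification route; the suite requires agreement within 1e-3 of `D` on
randomized bi-objective problems at 21 points per dimension.

Applied to the reference equations, the solver's optimum dominates the
reference settings: milk desirability saturates (the predicted yield
reaches the observed maximum) while intake stays moderate. The reported
reference optimum itself is kept as an evaluation point, not a target:
its intake value is not reproducible from the intake equation at the
stated settings (direct evaluation gives ≈ 22.3), and its temperature is
stated inconsistently in the source material (22 °C in one table, 20 °C
elsewhere; only 20 °C reproduces the stated milk fit of 61.145 L, so
20 °C is used in the worked example and the 22 °C variant is documented
as giving 60.94 L).

## Numerical choices and degenerate inputs

* Moment calibration tolerance: relative residual 1e-5 on mean/SD;
  failure is a classed error naming the factor.
* Near-zero spread specs degenerate gracefully: the quadrature window
  follows the distribution's own scale, so `sd -> 0` concentrates all
  mass at the mean.
* `implied_residual_sd()`'s floor (`1e-6 * target_variance`) keeps the
  generator defined when a hypothetical equation over-explains the
  target variance.
* Desirability at exactly an anchor is 0 or 1 (closed ends); `D = 0`
  exactly when some individual desirability is 0, and an all-zero search
  returns the best zero-`D` point flagged `converged = FALSE`.
* Pipeline artifacts embed the seed and a config hash, and all written
  CSV bodies are byte-stable under a repeated run.

## Limitations

The linear main-effects model is the object of study, not a claim about
dairy biology: curvature, factor interactions and per-cow heterogeneity
are out of scope, as are mixed-effects structures and heteroscedastic
errors. The optimizer certifies nothing globally — composite
desirability over linear responses is well behaved in practice and is
cross-checked against exhaustive grids, but no convexity argument is
offered. Grouped descriptive output reproduces the *shape* of the
reference age-group table only; several of its printed rows are
internally corrupted and are not reproduction targets.
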