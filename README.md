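# jointinput

Joint maximum-likelihood estimation of time-dependent input functions and
kinetic parameters in ODE models of biochemical reaction networks.

## The problem

Signalling models are driven by external stimuli — a hormone dose, a
phosphorylated receptor time course — that enter the ODE right-hand side as
a time-dependent input `u(t)`.  The input is itself measured, noisily and at
a handful of time points, yet the common workflow interpolates or smooths
the input data once, freezes the resulting curve, and fits the kinetic
parameters against the downstream data only.  That two-step ("standard")
procedure ignores the input measurement uncertainty: the parameter
confidence intervals come out too small, and their coverage falls below the
nominal level.

`jointinput` implements the joint ("comprehensive") alternative.  The input
is parametrized by the control points `v_1..v_N` of a natural cubic spline
with knots at the input measurement times; on log10 scale, so the
reconstructed input `u(t) = 10^{S(t)}` stays positive.  The control points
are appended to the parameter vector and the single objective

```
chi^2(theta, v) =  sum_ij [ (y_ij - y_i(t_j; theta, v)) / sigma_ij ]^2
                +  lambda * Integral S''(t)^2 dt
```

is minimized over everything at once — dynamic parameters, scaling/offset
parameters, initial concentrations and control points — where the data sum
runs over *all* observables including the input measurements, and the
curvature penalty (weight `lambda`, selected from the input data by a
chi-square discrepancy rule) keeps the estimated input from chasing noise.
All parameters are estimated on log10 scale.  Uncertainty is quantified by
profile likelihood: each parameter is scanned while all others are
re-optimized, and the points where the profile exceeds
`chi^2_min + qchisq(alpha, 1)` bound the confidence interval; a profile
that stays below the threshold up to a parameter bound yields an open
interval (practical non-identifiability, reported as `Inf`).

The package ships:

* a three-state illustrative mass-action model (`toy_model()`), a JAK2-STAT5
  signalling model with a discrete nuclear-residence delay
  (`jakstat_model()`, linear-chain or `dede` backends), and declarative YAML
  model configs (`model_from_config()`);
* the synthetic-data generator of the simulation study
  (`study_design()`, `generate_realization()`): Gaussian-bell input peaking
  at 100 at t = 25, N = 12 equidistant sampling times on [0, 50], log10
  observables with additive Gaussian noise (sigma = 0.1 states / 0.3 input);
* both estimators (`fit_model()`, approaches `"standard"` and
  `"comprehensive"`) with bound-constrained Levenberg–Marquardt least
  squares and Latin-hypercube multistart (`lhs_starts()`);
* profile-likelihood confidence intervals (`profile_fit()`,
  `confidence_interval()`);
* a Monte-Carlo assessment harness (`run_study()`) with the four criteria
  accuracy, precision, trajectory score and coverage, plus broom-style
  `tidy()`/`glance()` methods and `autoplot()` figures for every result
  type.

## Worked example

```r
library(jointinput)

design <- study_design()                       # the simulation truth
dat    <- generate_realization(design, seed = 7)

tmpl  <- parameter_set(dynamic = design$dynamic, initial = design$initial)
fit_c <- fit_model(dat, toy_model(), tmpl, approach = "comprehensive",
                   lambda = 0)
fit_s <- fit_model(dat, toy_model(), tmpl, approach = "standard",
                   lambda = 0)

glance(fit_c)$objective   # 34.2  — joint misfit over all 48 residuals
glance(fit_s)$objective   # 55.1  — downstream misfit given the frozen input

dplyr::filter(tidy(fit_c), block == "dynamic")
#>   parameter block   estimate_log10 estimate
#> 1 k1        dynamic         -1.68    0.0207
#> 2 km1       dynamic          0.204   1.60
#> 3 k2        dynamic         -0.144   0.717
#> 4 km2       dynamic         -0.824   0.150

pr <- profile_fit(fit_c, c("k1", "km1"), alpha = 0.95)
confidence_interval(pr, 0.95)[, c("parameter", "conf_lb", "conf_ub")]
#>   parameter conf_lb conf_ub
#> 1 k1        0.00745   0.103
#> 2 km1       0.826     6.07
```

The true values behind this realization are k1 = 0.01, k−1 = 1, k2 = 0.5,
k−2 = 0.1: the point estimates scatter with the measurement noise, and the
profile intervals for the input-coupled rates k1 and k−1 are wide because
the joint fit propagates the (large, sigma_u = 0.3) input uncertainty into
them.  A standard-approach profile of the same parameters is markedly —
and, as the Monte-Carlo study shows, overoptimistically — narrower.

The Monte-Carlo comparison itself:

```r
mc <- run_study(M = 200, seed = 1)   # ~10 min: 200 fits of both approaches
tidy(mc)                             # accuracy, precision, precision ratios
tidy(mc, "coverage")                 # coverage ratio per alpha level
autoplot(mc, "coverage")
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/jointinput.R", package="jointinput"))')" \
    simulate --seed 1 --out data.tsv
# subcommands: simulate | fit | profile | mc-study | compare
```
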