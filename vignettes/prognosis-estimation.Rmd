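---
title: "Estimating survivor prognosis with hazard-driven differential equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating survivor prognosis with hazard-driven differential equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survode)
```

## The model

Every parameter in this package is a deterministic functional of
cause-specific cumulative hazards.  The common backbone is an integral
equation

$$X(t) = X(0) + \int_0^t F\!\big(X(s)\big)\,\mathrm dA(s),$$

where $A$ stacks $q$ integrator components — cumulative hazards, plus
optionally the reserved `time` component with $\mathrm dA = \mathrm dt$ —
and $F$ maps the current state to a $p \times q$ coefficient matrix.
Three systems ship with the package:

* **survival**: $p = 1$, $\mathrm dS = -S\,\mathrm dA$, $S(0) = 1$,
  driven by the all-cause hazard;
* **cumulative incidence**: state $(S, C^c, C^o)$ with
  $\mathrm dS = -S\,\mathrm dA^c - S\,\mathrm dA^o$,
  $\mathrm dC^c = S\,\mathrm dA^c$, $\mathrm dC^o = S\,\mathrm dA^o$;
* **survival integral**: state $(S, R)$ with $R(t) = \int_0^t S$,
  $\mathrm dR = S\,\mathrm dt$, feeding restricted mean residual
  lifetime.

Replacing $A$ by the Nelson–Aalen step function
$\hat A^j(t) = \sum_{s\le t} \mathrm dN^j(s)/Y(s)$ turns the integral
equation into a finite forward recursion over the event grid, with all
coefficients evaluated at the left limit.  For the survival system this
recursion reproduces the Kaplan–Meier estimator exactly — the test suite
asserts equality against an independent implementation at $10^{-12}$ —
so the framework is a strict generalisation of the classical estimators
rather than an approximation to them.

The covariance of the root-$n$ residual process solves a companion linear
recursion driven by the same increments,

$$\hat V(t) = \hat V(0) + \sum_j \int_0^t \big\{\hat V\,\nabla F_j^\top +
\nabla F_j\,\hat V\big\}\,\mathrm d\hat A^j
+ n \int_0^t F\,\mathrm d[B]\,F^\top,$$

where the optional-covariation increments are
$\Delta[B]_{ij} = \Delta\hat A^i \Delta\hat A^j$ for hazard components
and zero for anything involving the `time` component.  A cross-covariance
recursion propagates $\hat V(t, s)$ forward from the anchor
$\hat V(t,t) = \hat V(t)$, and the delta method gives the variance of any
smooth two-time-point functional $H(\hat X(t), \hat X(t+\Delta))$.  The
parameters exposed to users are exactly such functionals: the conditional
survival ratio $y_1/x_1$, the RMRL $(y_2-x_2)/x_1$, and four
cause-specific transforms of the incidence state.

### Assumptions

* **Independent censoring.**  Nelson–Aalen consistency, and hence
  everything downstream, assumes censoring carries no information about
  residual survival.  No censoring diagnostics are provided.
* **Deterministic initial values.**  Every shipped system starts from a
  known constant, so $\hat V(0) = 0$.  User-defined systems may supply a
  nonzero positive semidefinite `v0`.
* **Known population rates.**  Rate tables are treated as population
  constants: population curves carry zero sampling variance and
  cohort-vs-population contrasts inherit only the cohort variance.  This
  matches how national life tables are conventionally used; it slightly
  understates uncertainty if the table itself is estimated from a small
  population.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `delta` | 5 years | Width of the prognosis window $(t, t+\Delta]$; 5 years is the convention in conditional-survival reporting. |
| `t_grid` | event grid on $[0,\ \mathrm{horizon}-\Delta]$ | Base times of a curve.  The solved path is a step function, so evaluating on the event grid is exact; a coarser regular grid is cheaper for large cohorts and loses nothing between events. |
| `mesh_step` | 0.01 years | Spacing of the regular mesh added for the `time` component.  See the numerical notes: results are mesh-invariant for the shipped systems, so this controls only the resolution of stored grid points. |
| `conf_level`, `ci_scale` | 0.95, `"plain"` | Wald intervals on the natural scale, clipped to the parameter's logical range ($[0,1]$ for probabilities, $[0,\Delta]$ for RMRL).  `"log"` and `"loglog"` transformations are available; plain intervals are the default because the variance estimator is reported on the natural scale. |
| `levels` | 0.6, 0.7, 0.8, 0.9, 0.95, 1 | Prognosis levels for the crossing-time report. |

## Numerical choices

**Left-limit evaluation.**  $F$ and $\nabla F_j$ are evaluated at the
previous grid point's state throughout, as the defining recursions
prescribe.  No predictor–corrector refinement is applied: the plug-in
recursion *is* the estimator, not a numerical scheme approximating one.

**Ties.**  Simultaneous events are pooled
($\Delta\hat A = \mathrm dN/Y$, possibly with $\mathrm dN > 1$), and
subjects censored exactly at an event time remain in the risk set.  Under
ties, $\Delta[B] = (\Delta\hat A)^2$ is taken as the definition; the
identity $[B](t) = \int_0^t Y^{-1}\mathrm d\hat A$ holds only for
singleton jumps and is asserted in tests only on tie-free data.

**Time component: exact interval propagation.**  Between event atoms the
covariance satisfies a linear matrix ODE in the `time` component,
$\mathrm d\hat V = (\hat V G^\top + G\hat V)\,\mathrm dt$ with
$G = \nabla F_{\mathrm{time}}$.  Instead of a left-point Euler sum
(whose $O(h)$ error would make results depend on the mesh), each grid
spacing $h$ is propagated exactly as
$\hat V \leftarrow (I + Gh)\,\hat V\,(I + Gh)^\top$: for the shipped
systems $G$ is state-independent and nilpotent, so $(I+Gh)$ equals the
exact matrix exponential and composes exactly across mesh refinements.
The same one-sided factor is used in the cross-covariance recursion, and
state components driven by $\mathrm dt$ are advanced linearly within an
interval (exact, because their coefficients are step functions).
Consequence: halving `mesh_step` changes $\hat R$ and every covariance at
floating-point level only, which the test suite asserts at $10^{-6}$
relative with margin to spare.

**Dual-route variances.**  Each shipped curve computes its variance twice
— once through the generic recursion/delta-method engine and once through
the explicit closed-form expression for that parameter (the scalar
survival recursion, the conditional-survival ratio form, the RMRL block
quadratic form, and the gradient quadratic forms for the four
cause-specific transforms).  The two routes must agree to $10^{-10}$
($10^{-12}$ for conditional survival) at every base time; disagreement is
an error, not a warning.  This equivalence is the strongest available
internal check on the covariance machinery and is always on.

**Degenerate inputs.**  A base time with $\hat S(t) = 0$, an empty
cause-specific denominator ($\hat C^o$ or $\hat S$ unchanged over the
window) or any non-finite gradient yields a flagged `defined = FALSE`
row, never an exception: exhausted risk sets at long follow-up are
routine in registry data.  Negative variance entries within $10^{-10}$ of
zero (floating-point noise) are clamped to zero; covariance matrices are
symmetrized at every step.

**Crossing times.**  The time-until-prognosis report interpolates
linearly between adjacent grid points of the estimate and, separately, of
the lower confidence curve.  The lower-band crossing is reported as the
pessimistic ("95th percentile") time: on a rising curve the lower band
crosses any level later than the point estimate, which is the only
reading of a pointwise band consistent with reporting a later,
conservative time.  A bootstrap percentile of the crossing time would be
an alternative; it is noted, not implemented.  Non-monotone estimated
curves report the first crossing with a warning, since the report is only
meaningful for prognoses that improve with time survived.

**Population conditioning.**  Conditional population quantities are
computed from the marginal Ederer I curve
$S_g(t) = n^{-1}\sum_i S_i^*(t)$, i.e. $CS_g(t+\Delta\mid t) =
S_g(t+\Delta)/S_g(t)$, not by re-matching among population survivors at
$t$.  The two differ when the cohort's age mix among survivors shifts;
the marginal convention is the one used with registry rate tables and is
kept here.  Matching uses age at diagnosis, sex and calendar year of
diagnosis only.  Rate lookups use the floor of attained age and calendar
year (hazard constant on unit cells, integrated in closed form per
cell); trajectories leaving the table carry the boundary rate forward
with a warning.  The reader ingests hazards (deaths per person-year)
directly; tables published as yearly death probabilities $q$ should be
converted with $-\log(1-q)$ first, as documented in
`?read_ratetable`.

## What the synthetic generator emulates — and what it does not

`scenario()`/`generate_cohort()` produce registry-like cohorts: latent
cause-specific death times with constant or piecewise-constant hazards,
independent exponential censoring, administrative censoring at a fixed
follow-up, and demographics (uniform ages 30–60 at diagnosis, diagnosis
years 2001–2018, even sex split) drawn independently of survival.
Closed-form truths for every parameter are available through
`scenario_truth()`, verified against numerical quadrature at $10^{-8}$.

This supports sharp tests — oracle equality, parameter recovery within
Monte-Carlo error, interval coverage — but it is a deliberately idealised
world: hazards are piecewise flat, censoring is exactly independent,
demographics do not influence survival (a hazard-multiplier option exists
for exercising the population matching, without closed-form truth), and
there is no delayed entry, no frailty, no misclassified cause of death.
Passing tests therefore demonstrate correctness of the estimators under
their stated assumptions, not robustness to violations of those
assumptions in real registry data.

Study sizes used in the checked properties, chosen to keep every
quantity's Monte-Carlo error well inside its assertion band: recovery of
closed-form truths on a single cohort of $n = 2000$ (hazards 0.3/0.1,
censoring 0.1) within three standard errors; interval coverage on 1000
replicates of $n = 300$ (hazards 0.1/0.05, censoring 0.1, evaluated at
$t = 1$, $\Delta = 5$ — a moderate-mortality setting with risk sets of
order 60 and up at $t+\Delta$, where Wald asymptotics are plausible);
oracle and closed-form equivalences on corpora of 10–50 random cohorts of
up to 200 subjects.

## Known limitations

* Only Nelson–Aalen driving estimates: no covariate-adjusted (additive
  hazards) integrators, hence no covariate-adjusted prognosis curves.
* Pointwise intervals only; no simultaneous confidence bands.
* No smoothing: curves inherit the step structure of the underlying
  estimators, which is honest but visually rough for small cohorts.
* Population contrasts ignore rate-table sampling error, and Ederer II /
  Hakulinen expected-survival variants are not implemented.
* The parameters are predictive summaries conditioned on survival; they
  have no causal interpretation, being conditioned on a post-treatment
  state.
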