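---
title: "Testing treatment-by-period interaction in unidirectional switch designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing treatment-by-period interaction in unidirectional switch designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usdpower)
```

## The design family and the estimation problem

A unidirectional switch design (USD) observes `M` clusters over `T` periods;
each cluster starts on control and may switch to the intervention once, at
the start of one of the periods. With `T` periods there are `T + 1` switch
patterns, indexed by the number `h` of treated (final) periods: pattern 0 is
a pure control arm, pattern `T` a pure intervention arm, and the interior
patterns are the familiar stepped-wedge sequences. Fixing allocation
probabilities `p_0, ..., p_T` picks out the classical designs: the
parallel-group design (PGD, mass on the two pure patterns), the delayed-start
design (DSD, pure patterns plus one middle pattern `s`), the stepped-wedge
design (SWD, interior patterns only), and the full-pattern USD.

The scientific question here is not the average treatment effect but whether
the treatment effect varies over calendar periods — the treatment-by-period
interaction. Writing the cell mean as
`g(mu_ij) = mu0 + beta_j + (theta0 + delta_j) x_ij` with a reference period
(`beta_ref = delta_ref = 0`), the interaction block `delta_j` is identifiable
only if every period contains clusters on both arms. A pure SWD fails this:
it has `2T - 2` distinct (period, arm) cells for `2T` free parameters, which
is why interaction inference is unavailable for classical stepped wedges —
and why the pure patterns matter. `check_identifiability()` performs exactly
this count.

```{r}
check_identifiability(c(0, 4, 4, 4, 0))  # stepped wedge, T = 4
check_identifiability(usd_design("USDu", M = 48, T = 5))
```

## Allocations, optimal designs, and rounding

`usd_design()` builds the executable allocation for the studied variants.
The uniform variants split clusters equally over their supported patterns.
The "optimal" variants use the closed-form probabilities that minimise the
variance of the *average* treatment effect for a continuous outcome at large
`M` (they are not optimal for the interaction — that contrast is the point
of the power study): for the full-pattern USD,
`p_0 = p_T = (1 - rho + n rho) / [2 (1 - rho + n rho T)]` and all interior
patterns get `n rho / (1 - rho + n rho T)`; for the three-pattern DSD the
analogous expressions weight the middle pattern `s`. On the latent probit
scale the intraclass correlation is `rho = sigma_c^2 / (sigma_c^2 + 1)`.

Exact proportions times `M` are fractional, so integer allocations need a
rounding convention. We implement the two symmetric options for the USD as
interior-first rules — `USDo1`: round interior patterns down, the two pure
patterns share the remainder equally; `USDo2`: round patterns `1` and `T-1`
up, `2..T-2` down, pure patterns share the remainder — and for the DSD:
round `p_s M` and `p_T M` to the nearest integer, pattern 0 absorbs the
remainder. At moderate ICC these coincide with rounding the pure patterns up
(USDo1) or down (USDo2). We chose the interior-first formulation because it
yields one well-defined allocation for every ICC in the studied range
(0.17–0.44), where a pure-pattern-first rule can strand a non-even interior
remainder; across that whole range it reproduces the same six allocations,
e.g. `(6,9,9,9,9,6)` and `(5,10,9,9,10,5)` at `M = 48`. For configurations
where the interior remainder is odd, the extra cluster goes to pattern 0,
deterministically. The DSD middle pattern defaults to `s = 3` for `T = 5`
(configurable).

## The data-generating process

`simulate_usd_trial()` draws cross-sectional binary data from a probit mixed
model: conditional on a latent cluster effect, subject `k` of cluster `i` in
period `j` has success probability
`pnorm(mu0 + b_ij + beta_j + (theta0 + delta_j) x_ij)` with `n` fresh
subjects per cluster-period. Defaults follow the study conditions: `T = 5`,
`n = 50`, `beta_j = 0.2 (j - 3)`, `theta0 = -0.4`, reference period 3, and
interaction profiles `delta_j = -0.1 (j - 3)` (linear), `-0.1 |j - 3|`
(symmetric) or zero (null). Two latent structures are provided:
*exchangeable* (`b_ij = b_i ~ N(0, sigma_c2)`, constant over periods) and
*AR1* (`b_ij` multivariate normal with variance `sigma_c2` and correlation
`r^|j-k|`, drawn through the Cholesky factor of the correlation matrix — `T`
is small, so no recursion is needed).

Allocation of clusters to switch patterns can be handled two ways. With
`randomize = FALSE` the design's integer allocation is used verbatim —
useful for planning a specific trial. With `randomize = TRUE` each cluster
draws its pattern independently with probabilities `N_h / M`, which is the
defining property of this design family (clusters are *randomly allocated*
to patterns); the per-replicate pattern counts then fluctuate
multinomially around the design allocation, and the draw is repeated in the
rare event that a pure pattern comes out empty, so the interaction stays
identifiable. The distinction matters for operating characteristics:
randomized allocation adds between-replicate design variability, which
costs a few points of power at the interior-pattern designs, makes the
generalized score test visibly conservative there, and produces the
documented small-sample misbehaviour of GEE at extreme designs under the
AR1 structure. Our Monte-Carlo study cells use `randomize = TRUE`; the
rejection rates under fixed allocation are systematically a few points
higher at interior-pattern designs.

The intercept `mu0` is not dictated by the study conditions; we set
`mu0 = 0`, i.e. a 50% event rate at the reference period under control, and
expose it as a parameter. Rejection rates depend mildly on it; the
parallel-group cells we reproduce are consistent with this choice.

Because the link is probit and the random effect normal, the
population-averaged (marginal) coefficients are exactly the subject-specific
ones shrunk by `1 / sqrt(1 + sigma_c2)` (`marginal_params()`); this supplies
the truths against which marginal-model estimates are judged. The same
identity gives a closed-form oracle for cell event rates,
`pnorm((mu0 + beta_j + theta_j x) / sqrt(1 + sigma_c2))`, which the
simulator tests verify empirically.

What the generator does *not* emulate: closed cohorts (no repeated
subjects), covariates, missing data, staggered calendars, and cluster-size
variation. Passing tests therefore speak to the cross-sectional,
complete-panel setting only.

## The two analysis engines

**Subject-specific route** — `usd_glmm()` fits the random-intercept probit
GLMM by maximum likelihood. The one-dimensional cluster integral is
approximated by adaptive Gauss–Hermite quadrature: each cluster's integrand
is centred at its conditional mode and scaled by the local curvature
(found by a damped Newton iteration), so `nodes = 1` is exactly the Laplace
approximation and 9–25 nodes are indistinguishable to 1e-4 on data of this
size (tested). The default is 25 nodes; the Monte-Carlo driver uses 9.
`sigma_c2` is optimized as a log-variance, so it cannot go negative; fits
that push it to the boundary (`< 1e-8`) are flagged `boundary` and reported,
not failed. Gradients use the Fisher identity (posterior expectation of the
complete-data score) and the observed information comes from the Louis
identity, both evaluated with the same quadrature; the resulting model-based
covariance matches lme4's to a few percent on shared fixtures, and the
likelihood itself is tested against brute-force `integrate()` to 1e-6.
Starting values come from a pooled probit GLM with `sigma_c2 = 0.1`;
non-convergence triggers one deterministic retry from a perturbed start and
is otherwise flagged, never silently returned. Individual-level and
aggregated data give identical fits because the cluster-period count is a
binomial sufficient statistic; only the log-likelihood constant differs.

The interaction test is the joint Wald chi-squared on the `T - 1` interaction
contrasts with the model-based covariance (a cluster-robust sandwich built
from per-cluster scores is available via `sandwich = TRUE`); confidence
intervals are normal-quantile Wald intervals (infinite denominator df).

**Population-averaged route** — `usd_gee()` solves the GEE for the marginal
probit mean with an exchangeable working correlation over all observations
of a cluster, alternating Fisher scoring with moment estimation of the
dispersion (`Pearson chi-squared / (N - p)`) and of the working correlation
from Pearson residual cross-products. Aggregated counts enter as binomial
proportions with denominator weights. Inference uses the Liang–Zeger
sandwich; the estimating-function norm at the solution is stored and checked
(`eq_norm`). The dispersion is estimated by default (`scale = "fixed"` pins
it at 1) — the estimates, sandwich covariance and score test are invariant
to it; only the model-based covariance is affected. Two interaction tests
are provided: the robust Wald test on the interaction block, and the
generalized (Boos-type) score test, which evaluates the interaction
estimating function at the main-effects fit — with the working correlation
and dispersion re-estimated under that null — and uses the empirical
covariance of the per-cluster effective scores. The whole engine is verified
against statsmodels' GEE to 1e-5 (coefficients, robust SEs, score
statistic).

Deliberately *not* implemented, matching the study's scope: random slopes or
period-specific random effects in the analysis model (fitting the
random-intercept model to AR1 data is the studied misspecification), AR1 or
Toeplitz *working* correlations, and small-sample sandwich corrections
(Kauermann–Carroll, Mancl–DeRouen) — the plain empirical estimator's
under-coverage at `M = 48` is part of the phenomenon under study.

## The Monte-Carlo driver

`mc_run_cell()` simulates, optionally aggregates, fits the requested engines
and records estimates, standard errors and interaction-test p-values per
replicate. One master seed spawns one substream per replicate (replicate `k`
depends only on the master seed and `k`), so replicate sets are extensible
and any execution order gives identical records. Replicate-level failures
are excluded with a reason code and reported, never aborting a cell; the
summary denominators shrink accordingly. `mc_summarize()` computes bias
(against subject-specific truths for the GLMM, marginal truths for GEE),
empirical and mean reported SEs, Wald coverage, and rejection rates at
`alpha = 0.05` two-sided, attaching `sqrt(p (1 - p) / R)` Monte-Carlo
standard errors to every proportion. `mc_run_grid()` iterates cells from a
YAML/JSON configuration and writes a tidy summary table; the
`inst/cli/usdpower.R` script exposes `design` and `run` subcommands.

## Numerical and design choices

* Probabilities inside the likelihood are clamped to `[1e-12, 1 - 1e-12]`;
  the mode-finding Newton step is damped (capped at 3 latent-scale units)
  and the curvature floored, so extreme cells cannot derail a fit.
* Quadrature: 9 nodes in simulation studies (equal to 25 nodes to 1e-4 at
  `n = 50`, `T = 5`; the stability test asserts this), 25 by default for a
  single fit.
* Test suite and acceptance script run cells at 500 replicates — the
  reproduced proportions are compared at 3 Monte-Carlo standard errors; the
  original tables use 1000 replicates (MCSE 0.007 at the 5% level,
  0.016 at 50% power). The large-sample recovery checks use `M = 192`.
* The working-correlation moment estimator subtracts the parameter count in
  its denominators (the convention of the standard GEE implementations); at
  one observation per cluster the correlation is undefined and set to 0.
* Exchangeable and AR1 latent draws share a code path (`r -> 1` recovers the
  row-constant special case, tested by moments).

## Known limitations

Under the AR1 data-generating process the analysis GLMM is misspecified by
construction, and its *model-based* Wald test ignores the period-specific
latent noise: the model-based covariance understates the variance of the
interaction contrasts several-fold, so the test is strongly anticonservative
and its nominal power correspondingly inflated. The sandwich option
(`sandwich = TRUE`) restores consistency of the covariance, at the cost of
the usual small-sample liberality of empirical estimators at `M = 48`.
Mixed-model software that estimates a residual dispersion alongside the
random intercept (pseudo-likelihood schemes) largely absorbs this
misspecification, which is worth knowing when comparing against such
output; this package's GLMM is a maximum-likelihood fit without a
dispersion parameter. Users drawing conclusions under non-exchangeable
latent structures should rely on the GEE route, whose sandwich-based
generalized score test remains close to nominal there, rather than the
GLMM model-based test. Coverage of
GEE sandwich intervals sits a few percent below nominal at `M = 48`
(a small-sample property of the plain empirical estimator), and the
generalized score test becomes conservative as the allocation moves mass to
interior patterns.
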