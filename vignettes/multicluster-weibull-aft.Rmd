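---
title: "Multi-cluster Weibull AFT survival models with IID and Besag ICAR random effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cluster Weibull AFT survival models with IID and Besag ICAR random effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Age at sexual debut in a DHS-style survey is a time-to-event outcome with a
strongly clustered structure: respondents are nested in households, and
households in states whose effects are spatially correlated. Treating either
level as noise biases covariate effects and their uncertainty. `icarsurv`
fits a Bayesian accelerated-failure-time (AFT) model whose linear predictor
carries both cluster levels at once:

$$\log T_i = \alpha + x_i'\beta + u_{h(i)} + s_{g(i)} + \sigma W_i,$$

where $T_i$ is the respondent's debut age (right-censored administratively
at the threshold age, 17 years by default), $W_i$ is a standard extreme-value
error so that $T_i$ is Weibull with shape $k = 1/\sigma$ and scale
$\lambda_i = \exp(\eta_i)$, $u_h \sim \mathrm{N}(0, 1/\tau_u)$ is an IID
household frailty, and $s$ is a Besag intrinsic conditional autoregressive
(ICAR) field on the state adjacency graph. Event records contribute
$\log f(t_i)$ and censored records $\log S(t_i)$ to the likelihood.

A coefficient $\beta_j$ is reported as a *Weibull time ratio*
$\mathrm{TR} = e^{\beta_j}$: the multiplicative effect on the time scale.
Our convention is fixed as TR > 1 meaning *longer* time to the event
(delayed debut) and TR < 1 meaning earlier debut. The AFT form is used
throughout (rather than the proportional-hazards Weibull form) because the
quantity of interest is exactly this time ratio; the two parameterisations
are dual, with PH coefficient $-k\beta$, and the test suite asserts this
duality numerically.

## The ICAR prior

Conditionally, each state's effect is normal around the weighted mean of
its neighbours with precision $\tau_s \sum_{j \in N_i} w_{ij}$. Jointly this
is the improper pairwise-difference density with quadratic form
$Q(s) = \sum_{i \sim j} w_{ij} (s_i - s_j)^2 = s' L s$ for the weighted
graph Laplacian $L$. Two choices here were genuinely open:

* **Precision, not variance.** Applied statements of the Besag conditional
  are often ambiguous about whether the dispersion parameter is a precision
  or a variance; we adopt the precision reading ($\tau_s$ multiplies the
  quadratic form), which is the standard Besag parameterisation and the one
  under which the Gamma prior is conjugate.
* **Full pseudo-density.** `icar_logpdf()` evaluates the *proper* density
  on the per-component sum-to-zero subspace, including the rank
  $(n - c)/2$ power of $\tau_s$ and the generalized log-determinant of $L$
  (product of its nonzero eigenvalues, cached per graph). An unnormalised
  form would suffice for MCMC, but the determinant term is exactly what
  catches rank-deficiency bugs in tests: the density must agree with an
  independent eigenbasis construction of the constrained normal, and does,
  to 1e-8, on every connected graph with up to five nodes.

Rank deficiency is handled as rank $n - c$ with $c$ the number of
connected components; the field is constrained to sum to zero within each
component, and isolated nodes get effect exactly 0 (they carry no spatial
information). The AFT intercept and shape absorb the baseline; some
statements of this model family pair the additive predictor with a
lognormal baseline instead, but time-ratio reporting and the estimates
this package targets are Weibull, so Weibull is used throughout.

## Priors and defaults

| Parameter | Prior | Default | Why |
|---|---|---|---|
| intercept, $\beta$ | Normal(0, sd 10) | — | weakly informative on log-years |
| $\log k$ | Normal(0, sd 1) | — | shapes 0.1–10 plausible |
| $\tau_u$, $\tau_s$ | Gamma(shape, rate) | shape 1, rate 5e-5 | diffuse, INLA-like |
| censor threshold | — | 17 years | event definition: debut at or below 17 |

All are overridable through `model_spec()` / the `priors` argument of
`icar_aft()`. The four model variants (`none`, `iid`, `besag`,
`iid_besag`) differ only in which random effects enter; disabled terms
contribute exactly zero to the joint posterior.

## Inference

Models of this family are usually estimated with INLA; the model
contract is the posterior, not the approximation algorithm, so `icarsurv`
ships its own adaptive Metropolis-within-Gibbs sampler (`run_mcmc()`), and
any correctness claim is against the posterior itself (grid-quadrature
oracles, prior recovery, calibration experiments). One sweep updates:

1. the intercept and each coefficient by scalar Gaussian random walks;
2. $\log k$ by a scalar random walk;
3. each household frailty against only its own records' likelihood;
4. each state effect (several passes per sweep, `spatial_passes`; one pass
   costs about as much as one coefficient update), then the field is
   recentred; when households are strictly nested within states a *swap*
   move follows for each state, shifting mass between its spatial effect
   and the mean of its households' frailties — the likelihood is exactly
   invariant along that direction, so the move accepts on the prior ratio
   alone and decorrelates the otherwise slowest direction of the chain;
5. $\tau_u$, $\tau_s$ by conjugate Gamma draws:
   $\tau_u \sim \Gamma(a + H/2,\, b + \sum u_h^2/2)$ and
   $\tau_s \sim \Gamma(a + (n-c)/2,\, b + Q(s)/2)$.

Design notes, where the design was open:

* **Scalar rather than block fixed-effect updates.** With dummy-expanded
  designs of modest width, per-coordinate walks adapted to a 0.44
  acceptance target mix robustly without estimating a proposal covariance.
  Each proposal costs one vectorised likelihood pass, so a sweep is linear
  in $n$.
* **Spatial identifiability.** On a connected graph each sweep recentres
  the field and absorbs its mean into the intercept (hierarchical
  recentring, the standard device in CAR modelling). On a disconnected
  graph the extra component levels cannot all be absorbed by one
  intercept, so proposals are instead projected onto the sum-to-zero
  subspace, which targets the constrained posterior exactly. Either way,
  every stored draw satisfies the per-component zero-sum constraint by
  construction.
* **Adaptation** is Robbins–Monro on the log proposal scales and is
  frozen at the end of burn-in, preserving ergodicity.
* **Initialisation.** Coefficients start at a censoring-naive least-squares
  fit of log-time, $k$ at 1, effects at zero. Precisions start at 1, *not*
  at the diffuse prior's mean ($2\times10^4$): starting there pins the
  effects near zero and the conditional precision posterior stays enormous —
  a well-known slow-mixing trap for conjugate precision updates.
* Every kept draw stores the per-record log-likelihood vector, which is
  what DIC and WAIC consume.

Convergence is monitored by rank-normalised split-$\widehat R$ and
effective sample size across chains (`convergence_summary()`), flagging
$\widehat R > 1.01$.

## Model comparison

`dic()` uses the classic mean-deviance form: $pD = \bar D - D(\bar\theta)$
with $\bar\theta$ the component-wise posterior mean ($\log k$ averaged on
the log scale). `waic()` computes the log pointwise predictive density
with log-sum-exp stabilisation and the variance-based penalty, warning
when any record's pointwise variance exceeds 0.4. Absolute DIC/WAIC
values differ across implementations (INLA's effective-parameter count is
not the classic mean-deviance form used here), and the reference survey
microdata are restricted, so absolute criterion values are not
reproduction targets; the package's claim — verified in the acceptance
suite over 20 replicates — is the
*ordering*: on data carrying both clustering levels, the combined
IID + ICAR model attains the lowest DIC and WAIC against all three
ablations, and on data with no clustering the plain model is within
$2\,pD$ of the best.

## Proportional-hazards diagnostics

`cox_fit()` / `ph_test()` reproduce the workflow that motivates an AFT
choice: a Cox fit with Breslow ties and Grambsch–Therneau scaled
Schoenfeld tests, factors tested jointly with levels − 1 degrees of
freedom, plus a global test. The default time transform is the
Kaplan–Meier transform, the common software default, with identity
available by flag. These are standard steps and are delegated to the `survival`
package behind the module's interface; the test suite still checks the
partial-likelihood maximum against a hand-coded Breslow grid search, the
zero-sum estimating identity of the residuals, nominal type-I error under
proportional hazards, and power above 80% against a sign-flipping effect.

## The synthetic-data generator

The real survey microdata (127,546 respondents) are restricted, so
`simulate_dataset()` generates structurally faithful stand-ins with known
ground truth: households nested strictly within states (balanced
allocation by default, Dirichlet-random sizes optionally), covariates
drawn from frequency tables defaulting to the published descriptive
margins with true coefficients equal to the published posterior means,
frailties and an ICAR field at configured precisions, Weibull times by
inversion $T = e^{\eta}(-\log U)^{1/k}$, and administrative censoring at
the threshold. One seed determines everything, with per-stage sub-streams
so that each stage's draws are invariant to the others' draw counts.

What it does *not* emulate: the joint dependence between covariates (draws
are independent across covariates), survey weights and the two-stage DHS
sampling design, nonresponse, and reporting biases of self-reported debut
ages. Passing recovery tests therefore demonstrate correctness of the
estimator under the model, not robustness to those real-data features.
The published fitted shape is never reported, so the generator's default
$k = 2$ (rising hazard through adolescence) is a package choice; the
default intercept 2.895 is the published baseline, and default precisions
are $\tau_u = 4$, $\tau_s = 2$ (frailty sd 0.5, clearly visible spatial
structure). The default graph is a 6×6 rook lattice, a connected stand-in
for the 37-area national contiguity map, which is not bundled; users
supply their own edge list or GeoJSON for real maps.

## Numerical choices and degenerate inputs

* The sum-to-zero constraint is checked to a relative tolerance of 1e-8 in
  `icar_logpdf()`; `sample_icar()` projects draws back onto the constraint
  to remove eigenbasis rounding.
* Pointwise likelihood evaluation switches the event-density terms by the
  0/1 indicator arithmetically (no branching), and WAIC's lppd uses
  per-record max-shifting.
* TR bins are left-closed right-open; a TR exactly on a break joins the
  upper bin. The five default breaks (0.80, 0.95, 1.05, 1.25) are clean
  and symmetric; the `fig3` preset approximates the irregular verbal bands
  of the reference choropleth and is flagged approximate because the exact
  break values were never printed.
* Zero-record datasets are legal and recover the prior (tested); empty
  graphs are an error.
* Datasets with missing values are rejected with row-indexed errors;
  unknown household or state ids are named in indexing errors.

## Problem sizes used by the test and acceptance suites

The standard recovery experiment is 2,000 subjects in 100 households on a
5×5 lattice with true $\beta = (-0.5, 0.3)$, $k = 2$, $\tau_u = 4$,
$\tau_s = 2$; the acceptance suite runs 20 replicates of it (2,500-sweep
chains) for coverage, and 20 replicates of the four-variant comparison at
1,200 sweeps — chain lengths chosen as the shortest at which the
thinning-stability and calibration checks hold. The sampler-calibration
check uses 50 records and 20,000 kept draws against a 401×401 grid
quadrature. These sizes are the package's reference experiment, not
limits; `mcmc_control()` scales freely.

## Known limitations

* No left truncation, interval censoring, time-varying covariates or
  spline covariate effects; the single metric covariate in the reference
  analysis enters linearly, so smooth-term machinery is out of scope.
* The sampler is single-site Metropolis plus conjugate Gibbs: adequate at
  these problem sizes, but no HMC/NUTS; very large graphs or hundreds of
  thousands of records would want a different engine.
* DIC's $pD$ can differ from other software's effective-parameter counts;
  comparisons should use one implementation consistently.
* `export_choropleth()` renders a basic static map; it is not a GIS.
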