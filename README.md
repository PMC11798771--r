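# icarsurv

Bayesian multi-cluster survival analysis of age at sexual debut (or any
right-censored time-to-event outcome with two nested cluster levels):
a Weibull accelerated-failure-time (AFT) model whose linear predictor
combines fixed covariate effects, an IID Gaussian household frailty, and a
Besag intrinsic conditional autoregressive (ICAR) spatial effect on a
state adjacency graph. It is written for epidemiologists and
biostatisticians analysing DHS-style survey data, where respondents are
nested in households and households in spatially correlated states.

## The model

For respondent $i$ in household $h(i)$ and state $g(i)$:

$$\log T_i = \alpha + x_i'\beta + u_{h(i)} + s_{g(i)} + \sigma W_i$$

with $W_i$ standard extreme-value, so $T_i$ is Weibull with shape
$k = 1/\sigma$ and scale $\exp(\eta_i)$; debut ages above a threshold
(17 years by default) are administratively censored. The frailties are
$u_h \sim \mathrm{N}(0, 1/\tau_u)$ and $s$ follows the Besag ICAR prior
with density $\propto \tau_s^{(n-c)/2}\exp\!\big(-\tfrac{\tau_s}{2}
\sum_{i\sim j} w_{ij}(s_i-s_j)^2\big)$ on the per-component sum-to-zero
subspace. A coefficient is reported as a Weibull **time ratio**
$e^{\beta_j}$: TR > 1 means longer time to the event (delayed debut),
TR < 1 earlier debut. Inference is by an adaptive
Metropolis-within-Gibbs sampler; the four nested variants (no clustering,
IID only, ICAR only, both) are compared by DIC and WAIC computed from
pointwise posterior log-likelihoods. Cox/Schoenfeld diagnostics
(`cox_fit()`, `ph_test()`) reproduce the proportional-hazards checks that
motivate the AFT choice, and a synthetic-data generator
(`simulate_dataset()`) provides DHS-like clustered datasets with known
ground truth.

## Worked example

Simulate a clustered dataset with known truth (education coefficients
−0.136 / −0.317 / −0.843, urban 0.028, shape k = 2, frailty precision 4,
spatial precision 2) and fit the full model with two chains:

```r
library(icarsurv)

sim <- simulate_dataset(sim_config(
  n_subjects = 2000, n_households = 100, graph = make_lattice_graph(5, 5),
  covariates = list(
    education = list(type = "factor",
                     levels = c("none", "primary", "secondary", "higher"),
                     probs = c(0.50, 0.20, 0.24, 0.06),
                     beta = c(primary = -0.136, secondary = -0.317,
                              higher = -0.843)),
    residence = list(type = "factor", levels = c("rural", "urban"),
                     probs = c(0.35, 0.65), beta = c(urban = 0.028))),
  seed = 2026))

fit <- icar_aft(survival::Surv(time, event) ~ education + residence,
                sim$data, sim$graph,
                control = mcmc_control(iterations = 6000, burnin = 3000,
                                       thin = 3),
                chains = 2, seed = 1)
summary(fit)
```

```
Multi-cluster Weibull AFT model (iid_besag): 2000 records, 1261 events

Fixed effects (posterior means and Weibull time ratios)
             Effect Posterior mean    SD           95% CI Time ratio
        (Intercept)          2.901 0.058   [2.790, 3.015]
   educationprimary         -0.106 0.039 [-0.181, -0.029]       0.90
 educationsecondary         -0.294 0.037 [-0.369, -0.224]       0.75
    educationhigher         -0.859 0.059 [-0.971, -0.743]       0.42
     residenceurban          0.015 0.031  [-0.046, 0.076]       1.02

Weibull shape k (posterior mean): 1.955

Random-effect precisions:
                 parameter  mean         95% CI
 tau_u (frailty precision) 5.177 [3.379, 7.435]
    tau_s (ICAR precision) 1.610 [0.758, 3.042]

DIC 8203.05 (pD 93.4)   WAIC 8203.90 (p_waic 88.7)
All split-Rhat <= 1.01
```

Every generating value sits inside its 95% credible interval: higher
education multiplies time-to-debut by 0.42 (a 58% deceleration), the
frailty and spatial precisions are recovered, and the shape posterior
mean 1.955 matches the true k = 2. State-level effects export as a
binned table (and as GeoJSON via `export_choropleth()`):

```r
st <- bin_spatial_effects(spatial_effect_table(fit$samples, sim$graph))
head(st[order(st$time_ratio), c("state", "mean", "time_ratio", "bin_label")], 3)
```

```
   state       mean time_ratio           bin_label
5 r01c05 -1.0196080  0.3607363 strong_deceleration
1 r01c01 -0.7694859  0.4632511 strong_deceleration
4 r01c04 -0.7075391  0.4928556 strong_deceleration
```

A thin command line mirrors the same pipeline
(`inst/cli/icarsurv.R`: `simulate`, `fit`, `compare`, `ph-test`,
`report` subcommands), fully seed-deterministic.

## Layout

* `R/` — graph structures and the ICAR density (`graph.R`, `icar.R`);
  likelihood and joint posterior (`likelihood.R`); generator
  (`simulate.R`); sampler (`mcmc.R`, `convergence.R`); DIC/WAIC
  (`ic.R`); PH diagnostics (`ph.R`); reporting and choropleth export
  (`report.R`); the `icar_aft()` interface (`fit.R`); persistence and
  CLI (`persist.R`, `cli.R`).
* `vignettes/multicluster-weibull-aft.Rmd` — the methods vignette:
  model, priors, sampler design, what the generator does and does not
  emulate, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites.
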