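# aislmc

Annealed importance sampling (AIS) with Fisher-preconditioned Langevin
Monte Carlo transitions, for Bayesian parameter inference and model
evidence (marginal likelihood) estimation in nonlinear models — up to and
including a two-region neural mass model of event-related cortical
dynamics of the kind used in dynamic causal modelling of M/EEG data.

## What it computes

For a model with parameters $w$, Gaussian prior $p(w) = N(w;\mu,\Lambda)$
and likelihood $p(y\mid w)$, AIS bridges prior and posterior through
tempered densities $f_j(w) \propto p(y\mid w)^{\beta_j} p(w)$ along a
fifth-order geometric ladder $\beta_j = (j/J)^5$.  Each of $I$
independent *trajectories* starts from a prior draw, applies one
Metropolis-adjusted Langevin step per temperature with proposal

$$w^* \sim N\!\big(w + \tfrac12 C g_\beta,\; C\big), \qquad
  C = h^2 (\Lambda + \beta F)^{-1}, \quad h = 0.5,$$

where $g_\beta$ is the tempered log-joint gradient and $F$ the Fisher
information (for ODE models both come from forward sensitivity analysis),
and accumulates the log importance weight
$\log v = \sum_j (\beta_j - \beta_{j-1}) \log p(y \mid w_j)$.
The evidence estimate is $\log\hat Z = v_{\max} + \log\bar u$ with
bootstrap confidence intervals over trajectories; weighted endpoints are
posterior samples.  Prior-arithmetic-mean, posterior-harmonic-mean and
Gaussian importance-sampling estimators are included as the classical
baselines, and diagnostics cover weight entropy, significant-weight
counts, per-temperature acceptance rates and Royston's multivariate
normality test.

The built-in model zoo: conjugate linear regression (with exact posterior
and evidence oracles), a four-mode squared-coefficient regression, an
exponential approach-to-limit model, and single-/two-region neural mass
models with alpha-function synaptic kernels, sigmoidal firing rates,
Taylor-approximated delays, and analytic state/parameter Jacobians
(compiled, with a pure-R reference implementation).  Seeded generators
reproduce every simulated design.

## Worked example

Conjugate linear regression, where every AIS output can be checked
against closed-form values:

```r
library(aislmc)

gen <- gen_linear(seed = 1)          # 7 DCT regressors, N = 20, sigma = 0.2
fit <- fit_ais(gen$model, gen$data, run_config(J = 512, I = 32, seed = 1))
print(fit)
#> AIS fit of linear  (I = 32 , J = 512 )
#> log evidence: -14.168  [ -14.8868 , -13.6746 ] (5th-95th pct, 1000 bootstraps)
#> posterior mean: -1.914  0.687 -2.825  5.324  1.209 -2.801  1.361
#> weight entropy: 3.43 bits; I_q = 16
#> acceptance: a_high = 0.967  a_low = 0.969

linreg_analytic_evidence(gen$model, gen$data)
#> [1] -14.18892
```

The AIS estimate (−14.17) matches the analytic log evidence (−14.19)
within the bootstrap interval, 16 of 32 trajectories carry significant
weight, and acceptance stays high on this easy Gaussian target.  Model
comparison against the 6-regressor reduced model:

```r
fit_red <- fit_ais(gen$model_reduced, gen$data, run_config(J = 512, I = 32, seed = 1))
compare_evidence(fit, fit_red)
#> log BF (full vs reduced) = 25.99 [25.08, 27.01]   (analytic: 26.09)
```

The same driver runs the neural mass model: `gen_nmm(seed)` generates
two-region data at the canonical truth (strong forward and backward
connections, observation noise SD 0.01), `fit_ais()` with
`nmm_model(config)` or the generator's ready-made models estimates the 10
neurophysiological parameters and the evidence, and
`ais_diagnostics()` reports recovery RMSE and acceptance summaries.  A
thin command-line driver with `generate` / `fit` / `compare` /
`diagnose` subcommands lives at `inst/scripts/aislmc-cli.R`.

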