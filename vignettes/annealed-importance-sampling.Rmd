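---
title: "Annealed importance sampling with Langevin transitions: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annealed importance sampling with Langevin transitions: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aislmc)
```

## The inference problem

Given data $y$, a model with parameters $w$, a Gaussian prior
$p(w) = N(w; \mu, \Lambda)$ (mean $\mu$, *precision* $\Lambda$) and a
likelihood $p(y \mid w)$, the package estimates two things:

* the posterior $p(w \mid y)$, represented by weighted independent samples;
* the marginal likelihood (model evidence)
  $p(y) = \int p(y \mid w)\, p(w)\, dw$, whose ratio between two models is
  the Bayes factor used for model comparison.

For the nonlinear dynamical models the package is aimed at — notably
neural mass models of event-related cortical dynamics — the posterior may
be multimodal and non-Gaussian, which defeats Laplace-style local
approximations.  Annealed importance sampling (AIS) addresses both
problems at once: it explores the parameter space through a ladder of
tempered densities and yields an evidence estimator that is unbiased on
the natural scale.

## Annealed importance sampling

AIS bridges prior and posterior through the tempered densities

$$ f_j(w) \propto p(y \mid w)^{\beta_j}\, p(w), \qquad
   0 = \beta_0 < \beta_1 < \dots < \beta_J = 1 . $$

One *trajectory* draws $w_1$ from the prior, then applies, at each rung,
one Markov transition $T_{j-1}$ that leaves $f_{j-1}$ invariant, and
accumulates the log importance weight

$$ \log v = \sum_{j=1}^{J} (\beta_j - \beta_{j-1}) \log p(y \mid w_j). $$

Running $I$ independent trajectories gives endpoint samples
$w^{(i)}$ with normalised weights $q_i$; the evidence estimate is the
overflow-safe log-mean of the raw weights,
$\log \hat Z = v_{\max} + \log \bar u$ with
$u_i = \exp(\log v_i - v_{\max})$.  Confidence intervals are percentile
bootstraps (5th/95th) over trajectories, `n_boot = 1000` by default.

Two classical estimators are the two-temperature special cases: the prior
arithmetic mean (PAM, forward, underestimates in high dimensions because
prior draws miss the high-likelihood region) and the posterior harmonic
mean (PHM, reverse, overestimates because posterior draws miss the
low-likelihood region).  Both are provided as baselines
(`pam_evidence()`, `phm_evidence()`), along with importance sampling from
an arbitrary Gaussian proposal (`gaussian_is_evidence()`), which recovers
the evidence with vanishing variance when handed the exact posterior and
is the package's cross-check on the conjugate linear model.

**Schedule.** `make_schedule(J, order = 5)` uses the fifth-order geometric
ladder $\beta_j = (j/J)^5$.  The power-law concentrates rungs near the
prior end where the tempered density changes fastest; fifth order is the
package default everywhere, with $J = 512$ and $I = 32$ as the standard
operating point (`run_config()`).

**Weight indexing.** The rung-$j$ weight increment
$(\beta_j - \beta_{j-1}) \log p(y \mid w_j)$ uses the state *produced by*
the transition invariant at $\beta_{j-1}$; the initial increment uses the
prior draw.  This follows from the telescoping identity
$Z_J/Z_0 = \prod_j Z_{j+1}/Z_j$ with each ratio estimated under the
earlier temperature; with $J = 1$ the estimator reduces exactly to PAM
(an identity enforced by the test suite).

## Langevin transitions

Each transition is one Metropolis-adjusted Langevin (simplified manifold
MALA) step.  At inverse temperature $\beta$, with tempered log joint
$L_\beta(w) = \beta \log p(y \mid w) + \log p(w)$, gradient $g_\beta$, and
Fisher information $F$ of the likelihood at the current point, the
proposal is

$$ w^* \sim N(m, C), \qquad C = h^2 (\Lambda + \beta F)^{-1}, \qquad
   m = w + \tfrac{1}{2} C\, g_\beta , $$

with step size $h = 0.5$ fixed throughout.  The preconditioner is the
"simplified manifold" one: curvature is treated as locally constant and
recomputed once per step at the current point.

Two numerical choices matter here:

* **Full asymmetric correction.**  The reverse proposal density
  $q(w \mid w^*)$ is evaluated with $m, C$ rebuilt at $w^*$.  Because the
  preconditioner is position dependent, this is required for exact
  $f_\beta$-invariance; the test suite verifies invariance directly with a
  long chain against the conjugate posterior, and verifies that the
  acceptance log-ratio is exactly antisymmetric under exchanging the two
  points.
* **Jitter escalation.**  $\Lambda + \beta F$ is positive definite in
  exact arithmetic; if its Cholesky factorisation fails numerically, a
  diagonal jitter of $10^{-8}, 10^{-6}, 10^{-4}$ times the mean diagonal
  magnitude is added in turn, each escalation producing a warning.

Likelihood evaluation failures (ODE divergence, overflow) return
$-\infty$ with a structured marker (`eval_failure()`) rather than raising:
a failed proposal is simply rejected, which keeps trajectories alive in
the far tails at high temperature.  Only a trajectory whose *initial*
prior draw fails is dropped (and counted); more than 20% drops abort the
run.

**Reproducibility.** Each trajectory consumes its own L'Ecuyer-CMRG
substream derived from the root seed, so results cannot depend on how
trajectories are scheduled across workers.  Reverse (posterior-to-prior)
schedules are not implemented.

## The model zoo

All models expose the same contract (`bayes_model()`): prior,
log-likelihood, gradient, Fisher information, everything on an
unconstrained parameter scale.

**Conjugate linear regression** (`linear_model()`): $y = Xw + e$, known
noise SD, Gaussian prior; exact posterior and evidence
(`linreg_analytic_posterior()`, `linreg_analytic_evidence()`) serve as
oracles for every sampler property.  The canonical synthetic design
(`gen_linear()`) is $p = 7$ orthonormal DCT regressors over $N = 20$
points, noise SD $0.2$, prior variance 10 per coefficient, coefficients
drawn from the prior; the reduced model drops the last regressor.  The
DCT columns are unit-normalised (the convention of neuroimaging drift
bases); whether the original experiments normalised them is not
documentable, which shifts exact evidence values but no sampler
behaviour.

**Squared-coefficient regression** (`squared_model()`):
$y = X (w \circ w) + e$ with two DCT regressors.  Predictions are
invariant under sign flips of each $w_i$, so the posterior has four
symmetric modes — the standard multimodality stress test
(`gen_squared()`: truth $w = (2, 2)$, noise SD $0.5$).  The Fisher matrix
is the Gauss–Newton form $J^\top J / \sigma^2$ with
$J_{ni} = 2 w_i X_{ni}$.

**Approach-to-limit** (`approach_model()`):
$y(t) = -60 + V_a (1 - e^{-t/\tau})$, parameters $w_1 = \log \tau$,
$w_2 = \log V_a$, prior mean $(3, 1.6)$, precision $\mathrm{diag}(16,
16)$; the reduced variant keeps only $V_a$ and predicts a constant.  The
canonical generator uses $V_a = 30$, $\tau = 8$, unit noise variance on
$t = 1..20$ (the time grid is an implementer default; 20 points matches
the scale of the other regressions).  A note on the prior mean: paired
as printed it puts prior mass at $\tau \approx 20, V_a \approx 5$, while
the swapped pairing (`swap_prior_mean = TRUE`) centres it nearer the
canonical truth; the printed pairing is the default and the switch
exposes the ambiguity.

## The neural mass model

Each cortical region contains four populations — spiny stellate cells
(granular layer), excitatory and inhibitory synaptic input to pyramidal
cells, and inhibitory interneurons.  Mean firing rates follow the
shifted sigmoid

$$ s(x) = \frac{1}{1 + e^{-r_1 (x - r_2)}} - \frac{1}{1 + e^{r_1 r_2}}, $$

which vanishes at rest ($s(0) = 0$), making the all-zero state a fixed
point.  Rates become postsynaptic potentials by convolution with the
alpha kernel $h(t) = (H/\tau) t e^{-t/\tau}$, realised as the
second-order ODE $\ddot v = (H/\tau) \cdot \mathrm{input} - (2/\tau)
\dot v - v/\tau^2$; each of the four convolutions per region contributes
two states, and the pyramidal output potential $v_p = v_{pe} - v_{pi}$ is
integrated as a ninth state, so a region has $N_x = 9$ states and the
two-region network 18.  Signalling delays use the first-order Taylor
surrogate $\tilde v = v - \delta \dot v$ (no delay-differential solver),
with fixed intrinsic delays $\delta_{11} = \delta_{22} = 2$ ms and
estimable extrinsic delays.

Region 1 receives the exogenous input (a Gaussian bump peaking at 64 ms
with 16 ms width, entering through the rate function with a fixed gain —
see below) and a backward connection $a_{12}$ from region 2 targeting its
pyramidal and inhibitory populations; region 2 receives the forward
connection $a_{21}$ targeting its spiny stellate population.  This is the
standard hierarchical construction for event-related potential models.
Ten quantities are estimated — $a_{12}, a_{21}$, extrinsic delays
$\delta_{12}, \delta_{21}$, intrinsic gains $\gamma_{1..4}$ and rate
parameters $r_1, r_2$ (shared across regions) — each parameterised as
$\theta_k = \theta_{0k} e^{w_k}$ so that $w = 0$ gives the defaults and
positivity is automatic.  The prior over $w$ has zero mean and diagonal
covariance with variance 0.16 on the two connection strengths and 0.0625
on the rest.  The reduced model removes the backward connection; the
strength and delay of the absent connection then have prior-equal
posteriors and contribute factors of one to the evidence, so the
comparison is a genuine nested-model Bayes factor.

Observations are the two pyramidal potentials plus IID Gaussian noise
with known SD $\sigma_s$ per region (`nmm_log_lik()`).

**Fixed constants.** $H_e = 3.25$, $H_i = 22$ mV, $\tau_e = 10$,
$\tau_i = 20$ ms, intrinsic gain ratios $\gamma_{1..4} =
128 \cdot (1, 0.8, 0.25, 0.25)$, default extrinsic strengths
$(a_{12}, a_{21}) = (16, 32)$ and delays 16 ms — all taken from the
Jansen–Rit / ERP-modelling literature.  Two choices were set by a
one-time calibration of the package's own generator: the rate-function
defaults $r_1 = 2$ mV$^{-1}$ and $r_2 = 2$ mV, and the input gain
$g_u = 75$ with input amplitude 8.  The rate nonlinearity is bounded by one, so the input term
$s(u)$ alone cannot drive a realistic-amplitude response without an input
gain; $g_u$ plays the role of the subcortical input coefficient in ERP
models.  The calibration criterion was physiological self-consistency:
at the generating truth ($w_1 = w_2 = 1$, strong forward and backward
connections) the noise-free region-2 signal SD is $\approx 0.155$ mV, so
the canonical observation noise SD of 0.01 corresponds to a
signal-to-noise ratio near 16, and the response is a damped ERP-like
deflection peaking near 165 ms rather than a self-sustained oscillation.
These constants were fixed once and are exposed as `nmm_config()`
arguments.

**Gradients and Fisher information.**  The likelihood gradient and the
Gauss–Newton Fisher matrix come from forward sensitivities: the augmented
system $\dot S = (\partial f/\partial x) S + \partial f/\partial w$ is
integrated jointly with the states, and

$$ \nabla = \sum_t J_t^\top C_e^{-1} (y_t - \hat y_t), \qquad
   F = \sum_t J_t^\top C_e^{-1} J_t, \qquad
   J_t = \partial \hat y_t / \partial w . $$

Both Jacobians $\partial f/\partial x$ and $\partial f/\partial w$ are
analytic (including the rate-parameter derivatives and the delay terms)
and implemented twice: a reference implementation in R
(`nmm_derivatives()`) and a compiled one used by default; the test suite
pins them against each other at tight tolerances and pins the sensitivity
gradient against central finite differences of the log-likelihood.

**Integration.**  Stiff BDF integration (via \pkg{deSolve}) at relative
tolerance $10^{-2}$ and absolute tolerance $10^{-4}$, from the all-zero
initial state, with the analytic state Jacobian supplied to the implicit
solver; for the augmented system the solver receives the block-diagonal
approximation $I \otimes \partial f/\partial x$, which omits only
second-derivative coupling terms and therefore affects Newton convergence
speed, never accuracy.  Solver failures surface as evaluation failures
(rejected moves), and the generator refuses truths that fail to
integrate.

## Synthetic data and what it does (not) show

`gen_linear()`, `gen_squared()`, `gen_approach()` and `gen_nmm()`
reproduce the four canonical simulated designs, each returning data,
generating truth and ready-made models so that parameter-recovery tests
need no stored fixtures.  `gen_nmm()` accepts either a noise SD directly
(default 0.01) or a signal-to-noise ratio, defined as
$\mathrm{sd}(\text{noise-free region-2 signal}) / \sigma_s$ — the
definition that makes "very high SNR" consistent with a small noise SD.
Noise is IID across time and channels.

The generators emulate known-noise, directly-observed, two-region
simulated data.  They do not emulate real M/EEG: no lead-field projection
to sensors, no estimated noise variances, no trial-to-trial variability,
no temporally correlated noise, and only two regions.  Tests passing on
these generators therefore validate the inference machinery, not the
model's adequacy for empirical recordings.

## Diagnostics

* **Weight distribution:** entropy $-\sum q_i \log_2 q_i$ (maximum
  $\log_2 I$, e.g. 5 bits for $I = 32$) and $I_q$, the number of weights
  above 0.01.
* **Acceptance:** per-temperature means over trajectories, summarised
  over the high-temperature ($\beta < 0.5$) and low-temperature
  ($\beta \ge 0.5$) halves; the boundary is placed in the low half.
* **Royston's multivariate normality test** on endpoint samples:
  per-margin Shapiro–Wilk statistics mapped through Royston's 1992
  normalizing transformation, combined with equivalent degrees of freedom
  from the average transformed inter-margin correlation, referred to a
  $\chi^2_e$ distribution.  Valid for $3 \le n \le 2000$; for one
  dimension it reproduces the Shapiro–Wilk p-value exactly.  Raw p-values
  are reported together with a Bonferroni-corrected flag (default family
  size 40 at level 0.05, i.e. threshold $1.25 \times 10^{-3}$).
* **RMSE** between posterior mean and generating truth.  The posterior
  mean defaults to the self-normalised importance-weighted estimator;
  the unweighted mean over trajectory endpoints is available via
  `weighted = FALSE`.

## Problem sizes and operating characteristics

The default operating point is $J = 512$, $I = 32$.  The package's own
checks run the conjugate and squared-coefficient problems at that scale,
and the neural-mass problem at a scaled setting of $I = 8$ trajectories
with $J = 128$ temperatures on the default 301-point, 0–300 ms grid —
sizes chosen so the whole behavioural suite completes in a few minutes on
one core while still exercising every code path at meaningful precision.

Two operating characteristics deserve honest comment.  First, with one
Langevin step per rung at $h = 0.5$, the chain contracts towards the
moving tempered target by roughly a factor $1 - h^2/2$ per step, so at
coarse ladders the trajectory lags the target and the importance weights
spread: on the conjugate benchmark the weight SD is roughly 5.5 nats at
$J = 128$ against a perfect-transition floor of 1.3, which biases the
log-evidence estimate downward by about one nat there, shrinking to a
few tenths at $J = 512$.  Finer ladders, not larger $I$, are the remedy.
Second, on the scaled neural-mass runs the mean acceptance rates are
roughly 0.45–0.6 at high temperatures falling to 0.2–0.5 at low
temperatures depending on the data realisation — the expected monotone
profile, sitting somewhat above the rates one would see with a rougher
posterior geometry.

## Known limitations

* Evidence estimates at coarse ladders ($J \lesssim 256$) carry the
  negative bias discussed above; use $J = 512$ (the default) or finer.
* The Fisher preconditioner assumes a Gauss–Newton-like likelihood;
  models supplying a poor Fisher approximation will mix more slowly,
  though invariance is unaffected.
* Royston's test requires $3 \le n \le 2000$ samples and non-degenerate
  margins; with $I = 32$ trajectories its power against mild
  non-Gaussianity is limited (it is decisive for the four-mode posterior).
* The neural-mass architecture is fixed at one or two regions with the
  connection targets described above; lead fields, noise-variance
  estimation and larger networks are out of scope.
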