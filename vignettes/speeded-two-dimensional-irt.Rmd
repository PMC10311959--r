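---
title: "Joint modelling of ability and test completion under time limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of ability and test completion under time limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speededirt)
```

## The problem

When a test carries a strict time limit, most respondents never reach the
last items. Observed sum scores then mix two different person
characteristics: the ability the test is meant to measure, and a working
speed ("completion") component that determines how far into the test the
respondent gets. If groups — for example women and men — differ in the
completion component, group comparisons on sum scores are confounded and
the missingness produced by the time limit is *nonignorable*: it is
correlated with the latent quantities being estimated, so dropping or
zero-filling the missing cells biases every downstream estimate.

`speededirt` treats the two components as separate, correlated latent
traits and measures each from its own data channel.

## The model

For person $n$ and item $k$ (items in administration order, $k = 1..K$):

**Missingness indicators.** Each response cell is recoded into an
indicator $d_{nk}$: cells up to and including the last observed response
get $1$ (this deliberately scores *skipped* items — unanswered items
followed by later answers — as attempted), the first item of the terminal
unanswered run gets $0$, and everything after it is structurally missing
and carries no information. `code_missingness()` performs this coding.

**Completion channel.** A Rasch model on the indicators measures the
latent completion factor $\theta_{n0}$:
$$P(d_{nk} = 1) = \mathrm{logit}^{-1}(\theta_{n0} - \beta_{k0}), \qquad
  \beta_{k0} = \tau_0 + (k - K)\,\tau_1 .$$
The linear constraint on the completion difficulties makes the drop in
attempt probability uniform across item positions: with $\tau_1 > 0$,
early items are easier to reach. The likelihood of an indicator row is
exactly the law of a sequential stopping process — continue past item $k$
with probability $p_k(\theta_{n0})$, stop at the first failure — which is
also how the synthetic-data generator produces sessions. The equivalence
is verified against exhaustive enumeration for $K \le 3$ in the test
suite.

**Ability channel.** A second Rasch model on the observed scored
responses measures ability $\theta_{n1}$ with free item difficulties
$b_k$. Only observed responses enter this likelihood: skipped and
non-reached cells contribute nothing (they are *not* scored wrong in the
model; a `missing_as_wrong` convention exists only for descriptive sum
scores and Cronbach's alpha).

**Joint structure.** $(\theta_{n1}, \theta_{n0})$ is bivariate normal
with covariance $\Sigma$; the correlation
$r = \sigma_{10} / \sqrt{\sigma_1^2 \sigma_0^2}$ is the quantity of
scientific interest. Latent means are fixed at $0$ for identification
(the Rasch kernel is shift-invariant). With person covariates (Models
2–4: gender main effect, condition main effect, both plus interaction)
the latent means become linear in the dummies and the *reference group*
(men, control) is centred at $(0,0)$; the latent regression coefficients
are then directly comparable with observed-score gaps.

Everywhere in this package a latent 2-vector or $2\times2$ matrix is
ordered **(ability, completion)**.

## Priors

* $\tau_1 \sim N(0, 10)$ read as mean/variance; a `scale_is = "precision"`
  switch reinterprets the 10 for sensitivity analysis. $\tau_0$ is fixed
  at 1 by default (a location fixed inside the linear constraint is
  unusual but is the package's stated default; `tau0_free = TRUE` frees
  it).
* $b_k \sim N(0, \sigma_b)$ with $\sigma_b \sim$ InvGamma(0.1, 0.1)
  placed on the *standard deviation*; `sigma_b_on = "variance"` moves it
  to the variance, the more conventional choice.
* The latent precision $\Sigma^{-1} \sim$ Wishart$(\Omega, d+1)$ with
  $d = 2$. The scale matrix is not pinned down by convention, so
  $\Omega = I_2$ is used: with $df = 3$ this is weakly informative, and
  the implied prior on $\Sigma$ is heavy-tailed (its mean does not
  exist), which mildly favours larger variances in small samples.
* Regression coefficients $\sim N(0, 10)$ (variance reading, same switch).

## Estimation

`run_mcmc()` is a Metropolis-within-Gibbs sampler: person latent pairs
are updated by joint random-walk proposals vectorized over persons; item
difficulties by per-item random walks; $\tau_1$ and $\sigma_b$ by scalar
random walks ($\sigma_b$ on the log scale with the Jacobian); the latent
precision by its exact conjugate Wishart full conditional; and the
regression coefficients by their exact conjugate normal full conditional.
Proposal scales are tuned by Robbins–Monro batches of 50 *only during the
adaptation phase* (target acceptance 0.3 for the bivariate block, 0.44
for scalars); adaptation draws are never retained and burn-in follows
adaptation. The default iteration scheme is 3 chains of 25,000 adaptation
+ 25,000 burn-in, with 60,000 retained draws in total; a failed
convergence battery triggers one re-run with a 100,000-iteration burn-in
before `NOT_CONVERGED` is reported. Whether the retained total is split
across chains or applies per chain is configurable
(`total_is_per_chain`), since either reading of "a total of 60,000
iterations from three chains" is defensible; split-across is the default.

All randomness derives from one root seed; per-chain streams come
deterministically from `(seed, chain_id)`, so reruns are bit-identical.
Starting values are overdispersed: normals around prior means for
locations, uniforms over a range around 1 for variances
(`init_dispersion = 0` collapses every chain onto the prior means).

## Convergence battery and inference

`summarize_fit()` reports, per parameter: posterior mean, SD, 95% HPDI
(shortest sorted-sample window containing $\lceil 0.95 n \rceil$ draws,
checked against an exhaustive all-windows oracle), the classic
multi-chain Gelman–Rubin $\hat R$ (no split-chain, no rank
normalization), a Geyer initial-positive-sequence ESS pooled across
chains, and MCSE = SD/$\sqrt{ESS}$ — the MCSE definition is chosen
because the stated thresholds pair exactly at SD $\approx 1$:
$1/\sqrt{400} = 0.05$. The verdict is `NOT_CONVERGED` iff any parameter
has $\hat R > 1.05$, MCSE $> 0.05$ or ESS $< 400$, with the failing
parameters listed. ESS/MCSE are pooled across chains (recorded in the
report metadata). An effect is flagged when its HPDI excludes zero,
except variances, whose lower bound is zero by construction.

## What the generator emulates — and what it does not

`simulation_scenario()` defaults state the world the analysis assumes at
the motivating study's scale: $N = 794$, $K = 25$, 78% women, 50%
threat assignment, $\Sigma$ with ability variance 1.08, completion
variance 0.47 and covariance 0.26 ($r \approx .36$), item difficulties
drawn from $N(-0.64, 0.6^2)$ (centre and spread matching the printed
difficulty range), and a 5% intermediate-skip probability. The
completion-difficulty slope default $\tau_1 = 0.21$ was calibrated once,
numerically, so the expected attempted count under the stated $\Sigma$
matches the printed mean of 10.5 of 25 items; it was fixed before any
test outcome was observed and is not revisited.

The generator draws sessions from the sequential-Bernoulli reading of
the completion likelihood, so generated data follow the fitted model
*exactly* when `p_skip = 0`. Two honest gaps remain. First, with
`p_skip > 0`, a response that is skipped at the end of a session is
indistinguishable after coding from a non-reached item, so the coded
stopping point can sit below the true one; the generator stores both so
tests can quantify the ambiguity rather than hide it. Second, real
respondents are not a Rasch process: no item-content effects,
person-by-item interactions, response-time structure or nonlinear
condition effects are generated. A green recovery test therefore
establishes correctness of the estimation machinery under the model's
own assumptions — not robustness to their violation.

## Numerical choices and degenerate inputs

* Logistic log-probabilities are computed via `log1p(exp(·))` with a
  linear tail beyond $\eta > 35$, so likelihoods never overflow.
* A non-positive-definite $\Sigma$ evaluates to a $-\infty$ log prior (a
  rejected state), never an exception; the conjugate Wishart update can
  only produce positive-definite draws.
* Persons who attempted zero items are retained — their indicator row
  (`0` then structural missings) still informs the completion channel.
* Fully observed rows contribute no stopping event, only continuation
  events.
* HPDI ties are broken toward the earliest window; constant draws give a
  zero-width interval; fewer than 20 draws are refused.
* Degenerate chains (zero within-chain variance) are an error for
  $\hat R$ and return the total draw count for ESS (MCSE 0).

## Design decisions that were genuinely open

* The generic-sampler reading of the estimation scheme leaves the kernel
  unspecified; Metropolis-within-Gibbs with conjugate $\Sigma$ and
  coefficient blocks is the package's choice, and every block contract
  (iteration scheme, adaptation-only tuning, seed derivation) is
  independent of the kernel so a gradient-based engine could be swapped
  in behind `run_mcmc()`.
* The component models are implemented in their written Rasch (1PL)
  form; no discrimination parameters are estimated.
* Configs and manifests serialize as JSON (the environment provides no
  YAML reader); the shape of the interface is unchanged.
* The recovery and power harnesses evaluate their per-replicate
  convergence verdict on the monitored latent-covariance block by
  default: at scaled-down iteration budgets the ESS < 400 rule flags
  every parameter of every replicate, which would make the verdict
  vacuous. `monitor = "all"` restores the full battery.
* Both readings of the mean proportion correct (aggregate
  `sum(correct)/sum(answered)` and per-person averaged) are reported,
  as are attempted counts with and without intermediate skips, because
  the descriptive conventions are ambiguous in the source material.

## Known limitations

* The sampler is pure R. Vectorization keeps study-scale fits (N ≈ 800,
  K = 25, full default iteration scheme) in the tens-of-minutes range on
  one core; the scaled-down schemes used in the tests run in minutes.
* Random-walk updates of the latent pairs induce noticeable
  autocorrelation in the $\Sigma$ block; reaching ESS ≥ 400 on the
  covariance entries needs on the order of $10^4$ retained draws.
* Parameter recovery on a *single* dataset is limited by data-sampling
  noise (posterior SD ≈ 0.07–0.10 for the $\Sigma$ entries at N = 794),
  which no amount of MCMC can reduce; across replicates the estimators
  are unbiased (see the recovery harness).
* No DIC or other model-comparison criterion is computed; no DIF or
  response-time extensions are modelled.

## A worked example

```{r example, eval = FALSE}
library(speededirt)

# a study-scale synthetic cohort with a known gender gap on completion
sc <- simulation_scenario(N = 400, K = 25, beta = c(-0.18, -0.24), seed = 42)
ds <- generate_dataset(sc)
ind <- code_missingness(ds$response)

# observed layer: sum scores and Cohen's d
cov1 <- build_covariates(as.data.frame(ds$covariates), 1)
desc <- summarize_descriptives(ds$response, ind, cov1)
desc$cohens_d

# latent layer: Model 2 (gender on both traits), scaled-down chains
cfg <- mcmc_config(n_chains = 2, n_adapt = 1000, n_burnin = 1000,
                   n_posterior_total = 4000, seed = 42, escalate = FALSE)
fit <- fit_model(ds$response, ind, as.data.frame(ds$covariates), 2, cfg)
print(fit)
```
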