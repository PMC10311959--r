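# speededirt

Joint Bayesian two-dimensional item response modelling for **speeded
tests** — tests whose time limit prevents most respondents from reaching
all items, so observed scores mix ability with working speed, and the
resulting missingness is *nonignorable* (correlated with the traits being
measured).

The package is for psychometricians and experimentalists who need to ask:
how much of an observed group gap on a timed test reflects the measured
ability, and how much reflects how far into the test people get?

## The model

Each response cell is recoded into a completion indicator: every reached
item (including deliberately skipped ones) scores 1, the first item of
the terminal non-reached run scores 0, and later items are structurally
missing. Two Rasch models are fitted jointly:

- **completion channel** — P(d_nk = 1) = logit⁻¹(θ_n0 − β_k0) with the
  linear position constraint β_k0 = τ0 + (k − K)·τ1, the likelihood of a
  sequential stopping process;
- **ability channel** — P(x_nk = 1) = logit⁻¹(θ_n1 − b_k) over observed
  responses only.

(θ_n1, θ_n0) is bivariate normal with covariance Σ under a
Wishart(I₂, 3) prior on the precision; the latent correlation
r = σ₁₀/√(σ₁²σ₀²) is the headline quantity. Latent means are fixed at 0;
Models 2–4 regress them on gender, experimental condition, and their
interaction, so latent gaps can be compared with observed Cohen's d gaps.
Estimation is adaptive Metropolis-within-Gibbs with conjugate blocks,
three overdispersed chains, and a convergence battery (R̂ > 1.05,
MCSE > 0.05, ESS < 400 ⇒ `NOT_CONVERGED`, with one automatic burn-in
escalation). A generative simulator of the stopping process supports
parameter-recovery and power experiments. See the vignette in
`vignettes/` for assumptions, priors, numerical choices and limitations.

## Worked example

```r
library(speededirt)

# synthetic cohort with a known gender gap on both latent traits
sc <- simulation_scenario(N = 400, K = 25, beta = c(-0.18, -0.24), seed = 42)
ds  <- generate_dataset(sc)
ind <- code_missingness(ds$response)

cov1 <- build_covariates(as.data.frame(ds$covariates), 1)
desc <- summarize_descriptives(ds$response, ind, cov1)
desc$cohens_d
#>     outcome       d ci_lower ci_upper  n1 n2 defined
#> 1 attempted -0.0801   -0.317    0.157 312 88    TRUE
#> 2   correct -0.0794   -0.316    0.157 312 88    TRUE

cfg <- mcmc_config(n_chains = 2, n_adapt = 1000, n_burnin = 1000,
                   n_posterior_total = 4000, seed = 42, escalate = FALSE)
fit <- fit_model(ds$response, ind, as.data.frame(ds$covariates), 2, cfg)
print(fit)
#> <fit_report> model 2 — NOT_CONVERGED
#> latent correlation r = 0.380 [0.082, 0.665]
#>        parameter    mean      sd hpdi_lower hpdi_upper rhat   ess    mcse   sig
#>             tau1  0.2074 0.00714     0.1955      0.222 1.01  31.1 0.00128  TRUE
#>          sigma_b  0.7227 0.13245     0.4927      0.999 1.00 180.7 0.00985    NA
#>      var_ability  0.9760 0.12501     0.7597      1.243 1.00 247.8 0.00794    NA
#>   var_completion  0.4050 0.12617     0.1861      0.664 1.27  44.6 0.01889    NA
#>       cov_latent  0.2337 0.09519     0.0346      0.412 1.00  62.8 0.01201  TRUE
#>     beta_ability  0.0352 0.12945    -0.2320      0.281 1.00  48.1 0.01866 FALSE
#>  beta_completion -0.0752 0.13427    -0.3349      0.176 1.03  28.2 0.02530 FALSE
#>         r_latent  0.3800 0.14926     0.0817      0.665 1.07  35.2 0.02516    NA
```

What the numbers mean: the cohort was generated with latent correlation
r ≈ .36 and the fit recovers `r_latent` 0.38 with an HPDI excluding 0 —
more able respondents drop out later. The covariance `cov_latent` is
credibly positive (`sig = TRUE`). The gender coefficients carry wide
intervals at N = 400 and this deliberately short demonstration run is
honestly flagged `NOT_CONVERGED` by the effective-sample-size rule — at
the full default iteration scheme (3 × 25,000 + 25,000 + 60,000 draws)
the battery is satisfied on data of this kind.

A full pipeline run (simulate → code → descriptives → Models 1–3 →
gap-decomposition report):

```r
mf <- run_manifest(scenario = sc, models = c(1, 2),
                   cfg = cfg, out_dir = "run1")
run_pipeline(mf)   # writes CSV/JSON reports + plots under run1/
```

## Command line

```sh
Rscript inst/cli/speededirt.R simulate --scenario sc.json --seed 7 --out data/
Rscript inst/cli/speededirt.R fit --model 2 --responses data/responses.csv \
        --covariates data/covariates.csv --config cfg.json --seed 7 --out out/
Rscript inst/cli/speededirt.R recover --replicates 10 --seed 7 --out out/
```
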