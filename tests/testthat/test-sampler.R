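test_that("mcmc_config validates its bookkeeping", {
  cfg <- mcmc_config(n_chains = 3, n_posterior_total = 60000)
  expect_identical(cfg$n_retained_per_chain, 20000L)
  expect_error(mcmc_config(n_chains = 3, n_posterior_total = 100), "divisible")
  expect_error(mcmc_config(n_adapt = 0), ">= 1")
  expect_error(mcmc_config(n_posterior_total = 0), ">= 1")
  expect_error(mcmc_config(init_dispersion = -1), ">= 0")
})

test_that("initialize_chain is deterministic, overdispersed, and collapsible", {
  spec <- model_spec(2, K = 10)
  s1 <- initialize_chain(spec, 50, chain_id = 1, seed = 7)
  s1b <- initialize_chain(spec, 50, chain_id = 1, seed = 7)
  expect_identical(s1, s1b)                        # same (seed, chain) -> same state
  s2 <- initialize_chain(spec, 50, chain_id = 2, seed = 7)
  expect_false(isTRUE(all.equal(s1$b, s2$b)))      # chains are overdispersed
  expect_false(isTRUE(all.equal(s1$Sigma, s2$Sigma)))
  expect_named(s1$coefs, c("beta_ability", "beta_completion"))

  z1 <- initialize_chain(spec, 50, 1, 7, init_dispersion = 0)
  z2 <- initialize_chain(spec, 50, 2, 7, init_dispersion = 0)
  expect_equal(z1$theta, z2$theta)                 # dispersion 0 -> prior means
  expect_equal(z1$b, z2$b)
  expect_equal(z1$Sigma, diag(2))
  expect_equal(unname(z1$coefs), c(0, 0))
})

test_that("run_mcmc bookkeeping and reproducibility contracts hold", {
  ds <- small_dataset(N = 25, K = 3, seed = 4)
  ind <- code_missingness(ds$response)
  spec <- model_spec(1, K = 3)
  cfg <- mcmc_config(n_chains = 3, n_adapt = 5, n_burnin = 5,
                     n_posterior_total = 3, seed = 2, escalate = FALSE)
  out <- run_mcmc(ds$response, ind, NULL, spec, cfg)
  expect_length(out$chains, 3L)
  expect_identical(nrow(out$chains[[1]]), 1L)      # exactly 1 retained per chain

  cfg2 <- fast_cfg(seed = 31, n_adapt = 30, n_burnin = 30, n_posterior_total = 60)
  a <- run_mcmc(ds$response, ind, NULL, spec, cfg2)
  b <- run_mcmc(ds$response, ind, NULL, spec, cfg2)
  expect_identical(a$chains, b$chains)             # bit-identical draws
  # every retained Sigma draw is positive-definite
  for (m in a$chains) {
    expect_true(all(m[, "var_ability"] * m[, "var_completion"] -
                      m[, "cov_latent"]^2 > 0))
  }
})

test_that("the Sigma block matches the closed-form conjugate posterior", {
  set.seed(10)
  R <- matrix(rnorm(400), 200, 2) %*% chol(matrix(c(1, 0.4, 0.4, 0.8), 2))
  prior <- prior_config()
  # closed form: precision ~ Wishart(df0 + N, Vn); E[Sigma^{-1}] = (df0+N) Vn
  Vn <- solve(solve(prior$wishart_scale) + crossprod(R))
  ET <- (prior$wishart_df + nrow(R)) * Vn
  draws <- replicate(4000, solve(speededirt:::draw_latent_cov(R, prior)))
  expect_equal(apply(draws, c(1, 2), mean), ET, tolerance = 0.02)
})

test_that("prior-only sampling reproduces prior moments", {
  # all cells carry no information: the posterior is the prior; N is kept
  # tiny so the theta <-> coefficient funnel does not throttle mixing
  N <- 6L; K <- 3L
  resp <- response_matrix(matrix(NA_integer_, N, K))
  ind <- structure(list(values = matrix(NA_integer_, N, K),
                        item_order = resp$item_order,
                        person_ids = resp$person_ids),
                   class = "indicator_matrix")
  cov <- build_covariates(data.frame(gender = rep(c(1, 0), 3), condition = 0), 2L)
  spec <- model_spec(2, K = K)
  cfg <- mcmc_config(n_chains = 2, n_adapt = 1500, n_burnin = 1000,
                     n_posterior_total = 12000, seed = 6, escalate = FALSE)
  out <- run_mcmc(resp, ind, cov, spec, cfg)
  ch_tau1 <- param_chains(out, "tau1")
  tau1 <- unlist(ch_tau1)
  # the random-walk block mixes slowly over a sd sqrt(10) prior, so bound the
  # mean by its own Monte-Carlo error rather than a fixed constant
  expect_lt(abs(mean(tau1)), 5 * mc_standard_error(ch_tau1))
  expect_equal(sd(tau1), sqrt(10), tolerance = 0.35)
  bcoef <- unlist(param_chains(out, "beta_ability"))  # conjugate draw: exact prior
  expect_lt(abs(mean(bcoef)), 0.5)
  expect_equal(sd(bcoef), sqrt(10), tolerance = 0.2)
})

test_that("run_mcmc validates inputs and names the failing block", {
  ds <- small_dataset(N = 20, K = 3, seed = 5)
  ind <- code_missingness(ds$response)
  expect_error(run_mcmc(ds$response, ind, NULL, model_spec(1, K = 7), fast_cfg()),
               "spec K")
  expect_error(run_mcmc(ds$response, ind, NULL, model_spec(2, K = 3), fast_cfg()),
               "needs covariates")
  cov_wrong <- build_covariates(data.frame(gender = rep(0:1, 10), condition = 0), 3L)
  expect_error(run_mcmc(ds$response, ind, cov_wrong, model_spec(2, K = 3), fast_cfg()),
               "does not match model")
})

test_that("short chains recover generating parameters on easy data", {
  ds <- small_dataset(N = 250, K = 12, seed = 21, p_skip = 0)
  ind <- code_missingness(ds$response)
  fit <- fit_model(ds$response, ind, NULL, 1,
                   fast_cfg(seed = 22, n_adapt = 250, n_burnin = 250,
                            n_posterior_total = 1000))
  s <- fit$summary
  expect_equal(s$mean[s$parameter == "tau1"], 0.21, tolerance = 0.25)
  expect_gt(s$mean[s$parameter == "cov_latent"], 0)  # positive latent covariance
  expect_equal(s$mean[s$parameter == "var_ability"], 1.08, tolerance = 0.5)
})

test_that("fit_model escalates once and reports honest non-convergence", {
  ds <- small_dataset(N = 50, K = 5, seed = 13)
  ind <- code_missingness(ds$response)
  cov <- as.data.frame(ds$covariates)
  # tiny model-4 run: the ESS rule must flag it; escalation re-runs once
  cfg <- mcmc_config(n_chains = 2, n_adapt = 40, n_burnin = 40,
                     n_posterior_total = 80, seed = 14,
                     escalate = TRUE, escalation_burnin = 60L)
  fit <- fit_model(ds$response, ind, cov, 4, cfg)
  expect_identical(fit$verdict, "NOT_CONVERGED")
  expect_true(fit$escalated)
  expect_gt(nrow(fit$failures), 0)
  expect_true(all(c("beta_ability", "delta_completion") %in% fit$summary$parameter))
  expect_error(fit_model(ds$response, ind, NULL, 2, cfg), "require")
})
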