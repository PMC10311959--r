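test_that("irf matches closed forms and is shift-invariant", {
  expect_equal(irf(1.3, 1.3), 0.5)
  expect_equal(irf(log(3), 0), 0.75)
  expect_equal(irf(2, 0), 0.8807971, tolerance = 1e-6)
  expect_equal(irf(1000, 0), 1)         # overflow-safe
  expect_equal(irf(-1000, 0), 0)
  th <- seq(-3, 3, 0.5)
  expect_true(all(diff(irf(th, 0.7)) > 0))  # strictly increasing in theta
  # adding c to theta and all difficulties changes nothing (identification)
  expect_equal(irf(th + 5.3, 0.7 + 5.3), irf(th, 0.7))
})

test_that("completion_difficulty is the affine position profile", {
  expect_equal(completion_difficulty(25, 25, 1.7, 0.3), 1.7)    # k = K -> tau0
  expect_equal(completion_difficulty(1:10, 10, 0.5, 0), rep(0.5, 10))
  expect_equal(completion_difficulty(1, 25, 1, 0.1), -1.4)
  b0 <- completion_difficulty(1:25, 25, 1, 0.2)
  expect_equal(diff(b0), rep(0.2, 24))  # uniform change across the test
  expect_error(completion_difficulty(0, 25, 1, 0.1), "out of range")
  expect_error(completion_difficulty(26, 25, 1, 0.1), "out of range")
})

test_that("loglik_ability sums observed Bernoulli terms only", {
  expect_equal(loglik_ability(c(NA, NA, NA), 0.7, c(1, 2, 3)), 0)
  expect_equal(loglik_ability(1, 0.4, 0.4), log(0.5))
  expect_equal(loglik_ability(c(1, 0, NA), 0, c(0, 0, 0)), 2 * log(0.5))
  # term-by-term oracle on a generic row
  row <- c(1, NA, 0, 1); b <- c(-0.5, 1, 0.3, 0.8); th <- 0.9
  want <- log(irf(th, b[1])) + log(1 - irf(th, b[3])) + log(irf(th, b[4]))
  expect_equal(loglik_ability(row, th, b), want)
  expect_error(loglik_ability(c(1, 0), 0, c(0, 0, 0)), "lengths differ")
})

test_that("loglik_completion scores steps, stop and structural missings", {
  expect_equal(loglik_completion(0L, theta0 = 1, tau0 = 1, tau1 = 0.4), log(0.5))
  expect_equal(loglik_completion(c(1, 1, 0), 0, 0, 0), 3 * log(0.5))
  expect_equal(loglik_completion(rep(1L, 10), 30, 1, 0.1), 0, tolerance = 1e-8)
  expect_error(loglik_completion(c(1, 0, 0), 0, 0, 0), "more than one 0")
  expect_error(loglik_completion(c(1, NA, 1), 0, 0, 0), "NA without")
  expect_error(loglik_completion(c(0, 1, NA), 0, 0, 0), "1 after")
})

test_that("loglik_completion equals the sequential stopping law (K <= 3)", {
  # enumeration oracle: P(attempt exactly a) = prod_{k<=a} p_k * (1 - p_{a+1})
  tau0 <- 0.4; tau1 <- 0.3; K <- 3L
  for (theta0 in c(-1, 0, 0.8)) {
    p <- irf(theta0, completion_difficulty(1:K, K, tau0, tau1))
    mass <- enumerate_stopping(p)
    rows <- list(c(0L, NA, NA), c(1L, 0L, NA), c(1L, 1L, 0L), c(1L, 1L, 1L))
    for (a in 0:K) {
      expect_equal(loglik_completion(rows[[a + 1L]], theta0, tau0, tau1),
                   log(mass[a + 1L]))
    }
    expect_equal(sum(mass), 1)
  }
})

test_that("expected counts are monotone in the latent traits", {
  K <- 3L
  e_att <- function(th0) {
    p <- irf(th0, completion_difficulty(1:K, K, 0.5, 0.2))
    sum(enumerate_stopping(p) * 0:K)
  }
  th <- seq(-2, 2, 0.5)
  expect_true(all(diff(vapply(th, e_att, numeric(1))) > 0))
  expect_true(all(diff(irf(th, -0.6)) > 0))  # expected correct per attempted item
})

test_that("latent_mean implements the active-set regression", {
  d0 <- matrix(numeric(0), 3, 0)
  expect_equal(latent_mean(d0, numeric(0), 1),
               matrix(0, 3, 2, dimnames = list(NULL, c("ability", "completion"))))
  # the headline gender effects reproduce as the women's mean shift
  mu <- latent_mean(matrix(1, 1, 1), c(beta_ability = -0.18, beta_completion = -0.24), 2)
  expect_equal(unname(mu[1, ]), c(-0.18, -0.24))
  cf <- c(beta_ability = 0.1, beta_completion = 0.1, gamma_ability = 0.1,
          gamma_completion = 0.1, delta_ability = 0.1, delta_completion = 0.1)
  mu4 <- latent_mean(matrix(c(1, 1, 1), 1, 3), cf, 4)
  expect_equal(unname(mu4[1, ]), c(0.3, 0.3))
  # reference category (men, control) is centred at (0, 0)
  expect_equal(unname(latent_mean(matrix(0, 1, 3), cf, 4)[1, ]), c(0, 0))
  expect_error(latent_mean(matrix(1, 1, 2), cf, 2), "expects")
})

test_that("log_prior matches an independently written density sum", {
  prior <- prior_config()
  th <- matrix(c(0.3, -0.2, 0.1, 0.5), 2, 2)
  params <- list(b = c(-0.5, 0.2), tau1 = 0.15, sigma_b = 0.8,
                 Sigma = matrix(c(1.2, 0.3, 0.3, 0.6), 2), theta = th)
  # oracle: write each density out by hand
  S <- params$Sigma; Tm <- solve(S)
  lgamma2 <- function(a) 0.5 * log(pi) + lgamma(a) + lgamma(a - 0.5)
  wish <- (3 - 2 - 1) / 2 * determinant(Tm)$modulus - sum(diag(Tm)) / 2 -
    3 * 2 / 2 * log(2) - 0 - lgamma2(1.5)
  invg <- 0.1 * log(0.1) - lgamma(0.1) - (0.1 + 1) * log(0.8) - 0.1 / 0.8
  mvn <- sum(apply(th, 1, function(x) {
    -log(2 * pi) - 0.5 * determinant(S)$modulus - 0.5 * (x %*% Tm %*% x)
  }))
  want <- dnorm(0.15, 0, sqrt(10), log = TRUE) +
    sum(dnorm(params$b, 0, 0.8, log = TRUE)) + invg + as.numeric(wish) + mvn
  expect_equal(log_prior(params, prior), want)

  # tau1 at the prior mode contributes the N(0,10) mode density
  p0 <- params; p0$tau1 <- 0
  expect_equal(log_prior(p0, prior) - log_prior(params, prior),
               dnorm(0, 0, sqrt(10), log = TRUE) - dnorm(0.15, 0, sqrt(10), log = TRUE))

  # boundary states are rejected with -Inf, not an exception
  bad <- params; bad$Sigma <- matrix(c(1, 1.1, 1.1, 1), 2)  # |r| > 1
  expect_identical(log_prior(bad, prior), -Inf)
  bad2 <- params; bad2$Sigma <- matrix(c(4, 2, 2, 1), 2)    # r = 1 boundary
  expect_identical(log_prior(bad2, prior), -Inf)
  bad3 <- params; bad3$sigma_b <- -1
  expect_identical(log_prior(bad3, prior), -Inf)
})

test_that("prior configuration switches change the densities as declared", {
  params <- list(b = 0.5, tau1 = 1, sigma_b = 0.8,
                 Sigma = diag(2), theta = matrix(0, 1, 2))
  lp_var <- log_prior(params, prior_config(scale_is = "variance"))
  lp_prec <- log_prior(params, prior_config(scale_is = "precision"))
  expect_equal(lp_prec - lp_var,
               dnorm(1, 0, sqrt(1 / 10), log = TRUE) - dnorm(1, 0, sqrt(10), log = TRUE))
  lp_sd <- log_prior(params, prior_config(sigma_b_on = "sd"))
  lp_v <- log_prior(params, prior_config(sigma_b_on = "variance"))
  expect_false(isTRUE(all.equal(lp_sd, lp_v)))
})

test_that("joint log-posterior is finite inside and -Inf at the boundary", {
  ds <- small_dataset(N = 20, K = 4, seed = 2)
  ind <- code_missingness(ds$response)
  params <- list(b = rep(0, 4), tau1 = 0.2, sigma_b = 1,
                 Sigma = matrix(c(1, 0.3, 0.3, 1), 2),
                 theta = matrix(0, 20, 2))
  lla <- sum(vapply(1:20, function(n)
    loglik_ability(ds$response$values[n, ], 0, params$b), numeric(1)))
  llc <- sum(vapply(1:20, function(n)
    loglik_completion(ind$values[n, ], 0, 0.2, 0.2), numeric(1)))
  expect_true(is.finite(lla + llc + log_prior(params, prior_config())))
})
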