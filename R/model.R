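#' Prior configuration for the joint two-dimensional model
#'
#' Defaults follow the weakly informative setup the model was designed with:
#' a normal prior with mean 0 and *variance* 10 on the completion-difficulty
#' slope `tau1` and on every regression coefficient (a switch reinterprets
#' the 10 as a precision for sensitivity checks); the completion-difficulty
#' intercept `tau0` fixed to 1 (a switch frees it); item difficulties
#' `b_k ~ N(0, sigma_b)` with an inverse-gamma(0.1, 0.1) hyperprior placed on
#' the *standard deviation* `sigma_b` (a switch moves it to the variance);
#' and a Wishart(I2, 3) prior on the 2x2 latent precision matrix. Latent
#' trait means are fixed at 0 for identification — with covariates, the
#' reference group (men, control) is centred.
#'
#' @param tau1_scale spread parameter of the `tau1` prior (default 10).
#' @param coef_scale spread parameter of the coefficient priors (default 10).
#' @param scale_is `"variance"` (default) or `"precision"`: how
#'   `tau1_scale`/`coef_scale` are read.
#' @param tau0 value the completion intercept is fixed to (default 1).
#' @param tau0_free free `tau0` for sensitivity analysis (default FALSE).
#' @param sigma_b_shape,sigma_b_rate inverse-gamma hyperparameters (0.1, 0.1).
#' @param sigma_b_on `"sd"` (default) or `"variance"`.
#' @param wishart_scale 2x2 scale matrix of the Wishart prior (default I2).
#' @param wishart_df degrees of freedom (default 3 = dimension + 1).
#' @return list of class `prior_config`.
#' @export
prior_config <- function(tau1_scale = 10, coef_scale = 10,
                         scale_is = c("variance", "precision"),
                         tau0 = 1, tau0_free = FALSE,
                         sigma_b_shape = 0.1, sigma_b_rate = 0.1,
                         sigma_b_on = c("sd", "variance"),
                         wishart_scale = diag(2), wishart_df = 3) {
  scale_is <- match.arg(scale_is)
  sigma_b_on <- match.arg(sigma_b_on)
  stopifnot(tau1_scale > 0, coef_scale > 0, sigma_b_shape > 0, sigma_b_rate > 0,
            is.matrix(wishart_scale), all(dim(wishart_scale) == 2L),
            wishart_df >= 2)
  tau1_var <- if (scale_is == "variance") tau1_scale else 1 / tau1_scale
  coef_var <- if (scale_is == "variance") coef_scale else 1 / coef_scale
  structure(list(tau1_var = tau1_var, coef_var = coef_var, scale_is = scale_is,
                 tau0 = tau0, tau0_free = tau0_free,
                 sigma_b_shape = sigma_b_shape, sigma_b_rate = sigma_b_rate,
                 sigma_b_on = sigma_b_on,
                 wishart_scale = wishart_scale, wishart_df = wishart_df),
            class = "prior_config")
}

#' Model specification
#'
#' Bundles the covariate design choice (Models 1-4), the number of items and
#' the prior settings. Model 1 has no covariates; Model 2 adds the gender
#' main effect on both latent traits; Model 3 the condition main effect;
#' Model 4 both main effects and their interaction.
#'
#' @param model_id integer 1..4.
#' @param K number of items.
#' @param prior a [prior_config()].
#' @return list of class `model_spec`.
#' @export
model_spec <- function(model_id, K, prior = prior_config()) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:4) stop("unknown model_id: must be 1, 2, 3 or 4")
  stopifnot(K >= 1L, inherits(prior, "prior_config"))
  structure(list(model_id = model_id, K = as.integer(K), prior = prior),
            class = "model_spec")
}

# names of the active regression coefficients per model, in design order;
# suffix _ability / _completion marks which trait the coefficient shifts
coef_names_for_model <- function(model_id) {
  base <- switch(model_id, character(0), "beta", "gamma", c("beta", "gamma", "delta"))
  if (!length(base)) return(character(0))
  as.vector(t(outer(base, c("ability", "completion"), paste, sep = "_")))
}

#' Rasch item response function
#'
#' `P(success) = exp(theta - beta) / (1 + exp(theta - beta))`, evaluated
#' overflow-safely; strictly increasing in `theta`. Used for both data
#' channels: correctness given ability, and item attempt given the
#' completion factor.
#'
#' @param theta person trait value(s).
#' @param beta item difficulty value(s).
#' @return probability in (0, 1), vectorized.
#' @export
irf <- function(theta, beta) stats::plogis(theta - beta)

#' Linearly constrained completion difficulty
#'
#' The completion difficulties are restricted to an affine function of item
#' position, `tau0 + (k - K) * tau1`, so the drop in attempt probability is
#' uniform across the test: for `tau1 > 0` earlier items are easier to reach.
#' At `k = K` the difficulty equals `tau0` exactly.
#'
#' @param k item position(s), 1..K.
#' @param K number of items.
#' @param tau0 intercept (difficulty of the last item).
#' @param tau1 slope per item position.
#' @return numeric difficulty value(s).
#' @export
completion_difficulty <- function(k, K, tau0, tau1) {
  if (any(k < 1L | k > K)) stop("item index out of range 1..K")
  tau0 + (k - K) * tau1
}

#' Log-likelihood of one person's scored responses
#'
#' Sum over items with an observed response of the Bernoulli log-likelihood
#' under the ability Rasch model; missing cells (skipped or not reached)
#' contribute nothing.
#'
#' @param resp_row responses in `{0, 1, NA}`, aligned with `b`.
#' @param theta1 ability value.
#' @param b item difficulties.
#' @return log-likelihood (0 for an all-missing row).
#' @export
loglik_ability <- function(resp_row, theta1, b) {
  if (length(resp_row) != length(b)) stop("resp_row and b lengths differ")
  obs <- !is.na(resp_row)
  if (!any(obs)) return(0)
  eta <- theta1 - b[obs]
  x <- resp_row[obs]
  sum(x * stats::plogis(eta, log.p = TRUE) +
        (1 - x) * stats::plogis(-eta, log.p = TRUE))
}

#' Log-likelihood of one person's completion indicators
#'
#' The indicator row encodes the sequential stopping process: each `1`
#' contributes `log p_k(theta0)`, the single `0` (stopping event)
#' contributes `log(1 - p_k(theta0))`, and structurally missing cells after
#' the stop contribute nothing. `p_k` uses the linearly constrained
#' completion difficulty.
#'
#' @param ind_row indicators in `{1, 0, NA}` satisfying the row invariants
#'   (at most one 0, only NA after it).
#' @param theta0 completion-factor value.
#' @param tau0,tau1 completion-difficulty parameters.
#' @param K number of items (defaults to the row length).
#' @return log-likelihood.
#' @export
loglik_completion <- function(ind_row, theta0, tau0, tau1, K = length(ind_row)) {
  if (length(ind_row) != K) stop("ind_row length does not match K")
  check_indicator_row(ind_row)
  obs <- !is.na(ind_row)
  if (!any(obs)) return(0)
  k <- which(obs)
  eta <- theta0 - completion_difficulty(k, K, tau0, tau1)
  dd <- ind_row[obs]
  sum(dd * stats::plogis(eta, log.p = TRUE) +
        (1 - dd) * stats::plogis(-eta, log.p = TRUE))
}

check_indicator_row <- function(ind_row) {
  zeros <- which(!is.na(ind_row) & ind_row == 0L)
  if (length(zeros) > 1L) stop("malformed indicator row: more than one 0")
  nas <- which(is.na(ind_row))
  if (length(nas)) {
    if (!length(zeros)) stop("malformed indicator row: NA without a stopping 0")
    if (any(nas < zeros)) stop("malformed indicator row: NA before the stopping 0")
  }
  if (length(zeros) && any(!is.na(ind_row) & ind_row == 1L &
                           seq_along(ind_row) > zeros)) {
    stop("malformed indicator row: 1 after the stopping 0")
  }
  invisible(TRUE)
}

#' Covariate-implied latent means
#'
#' `mu = (beta_1 g + gamma_1 c + delta_1 g c, beta_2 g + gamma_2 c +
#' delta_2 g c)` with the first component shifting ability and the second
#' the completion factor; terms outside the active set of the model are
#' identically zero, and the reference category (men, control) has mean
#' (0, 0).
#'
#' @param design design matrix rows from [design_matrix()] (N x p).
#' @param coefs named numeric vector of active coefficients (see
#'   [coef_names_for_model()]), e.g. `c(beta_ability=, beta_completion=)`.
#' @param model_id integer 1..4.
#' @return N x 2 matrix with columns `ability`, `completion`.
#' @export
latent_mean <- function(design, coefs, model_id) {
  design <- as.matrix(design)
  nm <- coef_names_for_model(model_id)
  p_expected <- length(nm) / 2L
  if (ncol(design) != p_expected) {
    stop(sprintf("design has %d columns but model %d expects %d",
                 ncol(design), model_id, p_expected))
  }
  if (p_expected == 0L) {
    return(matrix(0, nrow(design), 2L,
                  dimnames = list(NULL, c("ability", "completion"))))
  }
  if (!all(nm %in% names(coefs))) {
    stop("coefs must be named with: ", paste(nm, collapse = ", "))
  }
  C <- matrix(coefs[nm], nrow = p_expected, ncol = 2L, byrow = TRUE)
  mu <- design %*% C
  colnames(mu) <- c("ability", "completion")
  mu
}

# log density of the Wishart(V, df) distribution at 2x2 matrix W
# (scale parameterization: E[W] = df * V)
dwishart_log <- function(W, V, df) {
  d <- 2L
  ldW <- determinant(W, logarithm = TRUE)
  ldV <- determinant(V, logarithm = TRUE)
  if (ldW$sign <= 0) return(-Inf)
  lgamma2 <- 0.5 * log(pi) + lgamma(df / 2) + lgamma((df - 1) / 2)
  as.numeric((df - d - 1) / 2 * ldW$modulus -
               0.5 * sum(diag(solve(V, W))) -
               df * d / 2 * log(2) - df / 2 * ldV$modulus - lgamma2)
}

dinvgamma_log <- function(x, shape, rate) {
  if (x <= 0) return(-Inf)
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

# log density of N(mu, Sigma) for rows of theta (N x 2); Sigma 2x2
dmvnorm2_log <- function(theta, mu, Sigma) {
  det <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  if (det <= 0 || Sigma[1, 1] <= 0) return(rep(-Inf, nrow(theta)))
  r <- theta - mu
  q <- (Sigma[2, 2] * r[, 1]^2 - 2 * Sigma[1, 2] * r[, 1] * r[, 2] +
          Sigma[1, 1] * r[, 2]^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Joint log-prior of a full parameter state
#'
#' Sums the log prior densities: normal (mean 0) for `tau1` and every active
#' regression coefficient, `N(0, sigma_b)` for each item difficulty,
#' inverse-gamma for `sigma_b`, Wishart for the latent precision matrix
#' `solve(Sigma)`, and the bivariate normal density of each person's latent
#' pair given its covariate-implied mean. A non-positive-definite `Sigma`
#' yields `-Inf` (a rejected state), not an error.
#'
#' @param params list with elements `b`, `tau1`, `sigma_b`, `Sigma` (2x2),
#'   optionally `tau0`, `coefs` (named), `theta` (N x 2) and `mu` (N x 2).
#' @param prior a [prior_config()].
#' @param model_id integer 1..4 (determines the active coefficient set).
#' @return scalar log density (possibly `-Inf`).
#' @export
log_prior <- function(params, prior, model_id = 1L) {
  stopifnot(inherits(prior, "prior_config"))
  Sigma <- params$Sigma
  det <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  if (det <= 0 || Sigma[1, 1] <= 0 || Sigma[2, 2] <= 0) return(-Inf)
  if (params$sigma_b <= 0) return(-Inf)
  lp <- stats::dnorm(params$tau1, 0, sqrt(prior$tau1_var), log = TRUE)
  if (isTRUE(prior$tau0_free) && !is.null(params$tau0)) {
    lp <- lp + stats::dnorm(params$tau0, 0, sqrt(prior$tau1_var), log = TRUE)
  }
  lp <- lp + sum(stats::dnorm(params$b, 0, params$sigma_b, log = TRUE))
  sb <- if (prior$sigma_b_on == "sd") params$sigma_b else params$sigma_b^2
  lp <- lp + dinvgamma_log(sb, prior$sigma_b_shape, prior$sigma_b_rate)
  lp <- lp + dwishart_log(solve(Sigma), prior$wishart_scale, prior$wishart_df)
  nm <- coef_names_for_model(model_id)
  if (length(nm)) {
    if (!all(nm %in% names(params$coefs))) stop("missing coefficients for model ", model_id)
    lp <- lp + sum(stats::dnorm(params$coefs[nm], 0, sqrt(prior$coef_var), log = TRUE))
  }
  if (!is.null(params$theta)) {
    mu <- if (is.null(params$mu)) matrix(0, nrow(params$theta), 2L) else params$mu
    lp <- lp + sum(dmvnorm2_log(params$theta, mu, Sigma))
  }
  lp
}
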