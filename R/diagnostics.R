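#' Gelman-Rubin potential scale reduction factor
#'
#' Classic multi-chain PSRF (no split-chain, no rank normalization):
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B` the between-chain variance of chain means times `n`.
#'
#' @param chains list of numeric vectors, one per chain (>= 2 chains with
#'   >= 2 draws each).
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  chains <- as_chain_list(chains)
  m <- length(chains)
  if (m < 2L) stop("gelman_rubin needs at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 2L) stop("chains must have at least 2 draws")
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) stop("degenerate chains: within-chain variance is zero")
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

as_chain_list <- function(chains) {
  if (is.numeric(chains)) chains <- list(chains)
  if (!is.list(chains) || !all(vapply(chains, is.numeric, logical(1)))) {
    stop("chains must be a numeric vector or a list of numeric vectors")
  }
  chains
}

#' Effective sample size
#'
#' Autocorrelation-based ESS pooled across chains with Geyer's
#' initial-positive-sequence truncation: lag autocorrelations (averaged over
#' chains, using the pooled within-chain variance) are summed in adjacent
#' pairs until the first non-positive pair, and
#' `ESS = m * n / (-1 + 2 * sum(pairs))`, capped at the total draw count and
#' floored at 1. Degenerate (constant) chains return the total count.
#'
#' @param chains list of per-chain numeric vectors (or one vector).
#' @return scalar ESS.
#' @export
effective_sample_size <- function(chains) {
  chains <- as_chain_list(chains)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  m <- length(chains)
  total <- m * n
  if (n < 3L) return(total)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (!is.finite(W) || W == 0) return(total)
  lag_max <- n - 2L
  acv <- vapply(chains, function(x) {
    as.vector(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         type = "covariance", demean = TRUE)$acf)
  }, numeric(lag_max + 1L))
  rho <- rowMeans(acv) / W  # rho[1] is lag 0
  n_pairs <- (length(rho) - 1L) %/% 2L
  tau <- -1 + 2 * rho[1L]
  if (n_pairs >= 1L) {
    for (p in seq_len(n_pairs)) {
      g <- rho[2L * p] + rho[2L * p + 1L]
      if (g <= 0) break
      tau <- tau + 2 * g
    }
  }
  if (tau <= 0) return(total)
  max(1, min(total, total / tau))
}

#' Monte Carlo standard error of a posterior mean
#'
#' `MCSE = posterior SD / sqrt(ESS)`, with the posterior SD computed from
#' the pooled draws. A zero-variance parameter has MCSE 0.
#'
#' @param chains list of per-chain numeric vectors (or one vector).
#' @return scalar MCSE.
#' @export
mc_standard_error <- function(chains) {
  chains <- as_chain_list(chains)
  pooled <- unlist(chains, use.names = FALSE)
  s <- stats::sd(pooled)
  if (!is.finite(s) || s == 0) return(0)
  s / sqrt(effective_sample_size(chains))
}

#' Highest posterior density interval from draws
#'
#' The shortest contiguous window over the sorted draws containing
#' `ceiling(mass * n)` draws. For a symmetric unimodal sample this is close
#' to the central interval; for skewed posteriors it need not contain the
#' mean. An effect is conventionally flagged when the interval excludes 0
#' (variances excepted, their lower bound being 0 by construction).
#'
#' @param draws numeric vector (>= 20 draws).
#' @param mass interval mass in (0, 1), default 0.95.
#' @return named numeric `c(lower, upper)`.
#' @export
hpdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("mass must lie strictly between 0 and 1")
  }
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 20L) stop("hpdi needs at least 20 draws")
  s <- sort(draws)
  w <- ceiling(mass * n)
  if (w >= n) return(c(lower = s[1L], upper = s[n]))
  widths <- s[w:n] - s[1:(n - w + 1L)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + w - 1L])
}

#' Latent-trait correlation from (co)variance entries
#'
#' `r = cov / sqrt(var_ability * var_completion)`, vectorized over draws of
#' the latent covariance matrix.
#'
#' @param var_ability,var_completion,covariance numeric vectors (recycled).
#' @return numeric vector of correlations.
#' @export
latent_correlation <- function(var_ability, var_completion, covariance) {
  if (any(var_ability <= 0 | var_completion <= 0)) {
    stop("variances must be positive")
  }
  covariance / sqrt(var_ability * var_completion)
}

#' Convergence verdict over a diagnostics table
#'
#' A fit is `NOT_CONVERGED` iff any parameter has `R-hat > 1.05`, or
#' `MCSE > 0.05`, or `ESS < 400`; the failing parameters and rules are
#' listed, never silently dropped.
#'
#' @param summary_df data.frame with columns `parameter`, `rhat`, `ess`,
#'   `mcse`.
#' @param rhat_max,mcse_max,ess_min rule thresholds.
#' @return list with `verdict` (`"CONVERGED"`/`"NOT_CONVERGED"`) and
#'   `failures` (data.frame of parameter/rule/value rows).
#' @export
convergence_verdict <- function(summary_df, rhat_max = 1.05, mcse_max = 0.05,
                                ess_min = 400) {
  need <- c("parameter", "rhat", "ess", "mcse")
  if (!all(need %in% names(summary_df))) {
    stop("summary_df must have columns: ", paste(need, collapse = ", "))
  }
  fail <- list()
  flag <- function(rows, rule, value) {
    if (any(rows)) data.frame(parameter = summary_df$parameter[rows],
                              rule = rule, value = value[rows])
  }
  fail[[1]] <- flag(summary_df$rhat > rhat_max, sprintf("rhat > %.2f", rhat_max),
                    summary_df$rhat)
  fail[[2]] <- flag(summary_df$mcse > mcse_max, sprintf("mcse > %.2f", mcse_max),
                    summary_df$mcse)
  fail[[3]] <- flag(summary_df$ess < ess_min, sprintf("ess < %d", ess_min),
                    summary_df$ess)
  failures <- do.call(rbind, fail[!vapply(fail, is.null, logical(1))])
  if (is.null(failures)) failures <- data.frame(parameter = character(0),
                                                rule = character(0),
                                                value = numeric(0))
  list(verdict = if (nrow(failures)) "NOT_CONVERGED" else "CONVERGED",
       failures = failures)
}

#' Posterior summaries, diagnostics and verdict for a fit
#'
#' For every stored parameter: posterior mean, SD, 95% HPDI, R-hat, ESS and
#' MCSE (pooled across chains). The latent correlation is derived per draw
#' from the covariance entries and summarized alongside. Diagnostics for
#' all parameters feed the convergence verdict.
#'
#' @param draws a `posterior_draws` object from [run_mcmc()].
#' @param mass HPDI mass (default 0.95).
#' @param rhat_max,mcse_max,ess_min convergence rule thresholds.
#' @return An object of class `fit_report`: list with `summary`
#'   (per-parameter data.frame), `latent_correlation` (mean/sd/HPDI),
#'   `verdict`, `failures`, `escalated`, `model_id`, `seed`, `config`, and
#'   `metadata` recording the estimator conventions.
#' @export
summarize_fit <- function(draws, mass = 0.95, rhat_max = 1.05, mcse_max = 0.05,
                          ess_min = 400) {
  stopifnot(inherits(draws, "posterior_draws"))
  multi <- length(draws$chains) >= 2L
  one <- function(param) {
    ch <- param_chains(draws, param)
    pooled <- unlist(ch, use.names = FALSE)
    hp <- hpdi(pooled, mass)
    data.frame(parameter = param, mean = mean(pooled), sd = stats::sd(pooled),
               hpdi_lower = hp[[1L]], hpdi_upper = hp[[2L]],
               rhat = if (multi && stats::sd(pooled) > 0) gelman_rubin(ch) else NA_real_,
               ess = effective_sample_size(ch),
               mcse = mc_standard_error(ch))
  }
  smry <- do.call(rbind, lapply(draws$param_names, one))
  var_params <- c("var_ability", "var_completion", "sigma_b")
  smry$sig <- ifelse(smry$parameter %in% var_params, NA,
                     smry$hpdi_lower > 0 | smry$hpdi_upper < 0)

  r_chains <- lapply(draws$chains, function(m) {
    latent_correlation(m[, "var_ability"], m[, "var_completion"], m[, "cov_latent"])
  })
  r_pooled <- unlist(r_chains, use.names = FALSE)
  r_hp <- hpdi(r_pooled, mass)
  r_row <- data.frame(parameter = "r_latent", mean = mean(r_pooled),
                      sd = stats::sd(r_pooled),
                      hpdi_lower = r_hp[[1L]], hpdi_upper = r_hp[[2L]],
                      rhat = if (multi) gelman_rubin(r_chains) else NA_real_,
                      ess = effective_sample_size(r_chains),
                      mcse = mc_standard_error(r_chains), sig = NA)
  smry <- rbind(smry, r_row)

  rules <- smry[smry$parameter != "r_latent", ]
  rules$rhat[is.na(rules$rhat)] <- 1  # single chain: R-hat rule cannot fire
  verdict <- convergence_verdict(rules, rhat_max, mcse_max, ess_min)

  structure(list(summary = smry,
                 latent_correlation = list(mean = mean(r_pooled),
                                           sd = stats::sd(r_pooled),
                                           hpdi = r_hp),
                 verdict = verdict$verdict, failures = verdict$failures,
                 escalated = FALSE, model_id = draws$model_id,
                 seed = draws$seed, config = draws$config,
                 theta_mean = draws$theta_mean,
                 accept_rates = draws$accept_rates,
                 metadata = list(
                   rhat = "classic multi-chain PSRF, no split, no rank-normalization",
                   ess = "Geyer initial-positive-sequence, pooled across chains",
                   mcse = "posterior SD / sqrt(ESS), pooled",
                   coef_prior_scale = "N(0, scale) read as variance unless configured otherwise")),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> model %d — %s%s\n", x$model_id, x$verdict,
              if (isTRUE(x$escalated)) " (after burn-in escalation)" else ""))
  cat(sprintf("latent correlation r = %.3f [%.3f, %.3f]\n",
              x$latent_correlation$mean, x$latent_correlation$hpdi[[1L]],
              x$latent_correlation$hpdi[[2L]]))
  show <- x$summary[!grepl("^b\\[", x$summary$parameter), ]
  print(show, row.names = FALSE, digits = 3)
  if (nrow(x$failures)) {
    cat("failing rules:\n")
    print(x$failures, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write trace and posterior-density plots for a fit
#'
#' Reporting-only helper: one PNG per requested parameter with the
#' per-chain trace and the pooled posterior density. Skipped with a message
#' when no PNG device is available.
#'
#' @param draws a `posterior_draws` object.
#' @param dir output directory.
#' @param params parameters to plot (default: all non-item parameters).
#' @return invisibly, the paths written (possibly empty).
#' @export
plot_diagnostics <- function(draws, dir, params = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(params)) params <- grep("^b\\[", draws$param_names,
                                      value = TRUE, invert = TRUE)
  if (!capabilities("png")) {
    message("no PNG device available; skipping diagnostic plots")
    return(invisible(character(0)))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (p in params) {
    path <- file.path(dir, paste0("diag_", gsub("[^A-Za-z0-9_]", "_", p), ".png"))
    ok <- tryCatch({
      grDevices::png(path, width = 900, height = 400)
      on.exit(grDevices::dev.off(), add = TRUE)
      oldpar <- graphics::par(mfrow = c(1, 2))
      on.exit(graphics::par(oldpar), add = TRUE)
      ch <- param_chains(draws, p)
      graphics::plot(ch[[1L]], type = "l", col = 1, xlab = "iteration",
                     ylab = p, main = paste("trace:", p),
                     ylim = range(unlist(ch)))
      if (length(ch) > 1L) {
        for (i in 2:length(ch)) graphics::lines(ch[[i]], col = i)
      }
      pooled <- unlist(ch)
      graphics::plot(stats::density(pooled), main = paste("posterior:", p),
                     xlab = p)
      TRUE
    }, error = function(e) FALSE)
    if (ok) written <- c(written, path)
  }
  invisible(written)
}
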