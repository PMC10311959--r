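#' Run manifest
#'
#' Declares one reproducible analysis run: either a simulation scenario or
#' paths to response/covariate files, the models to fit, the MCMC
#' configuration and the output directory. Re-running an identical manifest
#' reproduces identical numerical outputs. The default model list is
#' `c(1, 2, 3)`; Model 4 (the interaction model) is opt-in because it is the
#' hardest to converge.
#'
#' @param scenario a [simulation_scenario()], or NULL when reading files.
#' @param responses,covariates input file paths (ignored when `scenario`
#'   is given).
#' @param models integer vector of model ids to fit.
#' @param cfg an [mcmc_config()].
#' @param out_dir output directory.
#' @param missing_token missing token of the response file.
#' @param women_label,threat_label label mapping for a covariate file.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(scenario = NULL, responses = NULL, covariates = NULL,
                         models = c(1L, 2L, 3L), cfg = mcmc_config(),
                         out_dir = tempfile("speededirt_run_"),
                         missing_token = "NA",
                         women_label = "women", threat_label = "threat") {
  if (is.null(scenario) && is.null(responses)) {
    stop("manifest needs either a scenario or a responses file path")
  }
  if (!all(models %in% 1:4)) stop("models must be a subset of 1..4")
  structure(list(scenario = scenario, responses = responses,
                 covariates = covariates, models = as.integer(models),
                 cfg = cfg, out_dir = out_dir, missing_token = missing_token,
                 women_label = women_label, threat_label = threat_label),
            class = "run_manifest")
}

stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %-12s %6.2fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Execute a full analysis run
#'
#' Stages: data (simulate or ingest) -> missingness coding -> descriptives
#' -> one fit per requested model -> reports. Writes, under the manifest's
#' output directory: the data files (when simulated), descriptive CSV/JSON
#' tables, a per-item proportion table, one fit-report JSON per model,
#' diagnostic plots when a PNG device exists, a gap-decomposition summary
#' juxtaposing observed-score gaps (Cohen's d) with latent-trait gaps
#' (gender coefficients on ability vs completion), a structured log and a
#' manifest echo listing every output file. Any stage failure halts the run
#' with the stage named and leaves a `FAILED` marker in the directory.
#'
#' @param manifest a [run_manifest()].
#' @param plots write diagnostic plots (default TRUE; auto-skipped without a
#'   PNG device).
#' @return invisibly, a list with the fits, the descriptive summary and the
#'   output directory.
#' @export
run_pipeline <- function(manifest, plots = TRUE) {
  stopifnot(inherits(manifest, "run_manifest"))
  out <- manifest$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  logf <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  files <- character(0)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(out, "FAILED"))
    stop(e)
  }
  withCallingHandlers({
    dat <- stage("data", logf, {
      if (!is.null(manifest$scenario)) {
        ds <- generate_dataset(manifest$scenario)
        files <- c(files, write_dataset(ds, out))
        list(resp = ds$response, cov_raw = ds$covariates, truth = ds$ground_truth)
      } else {
        resp <- read_response_matrix(manifest$responses,
                                     missing_token = manifest$missing_token,
                                     quiet = TRUE)
        cov_raw <- if (!is.null(manifest$covariates)) {
          utils::read.csv(manifest$covariates)
        } else NULL
        logf(sprintf("ingested N=%d persons (no upstream filter applied)",
                     nrow(resp$values)))
        list(resp = resp, cov_raw = cov_raw, truth = NULL)
      }
    })
    ind <- stage("coding", logf, code_missingness(dat$resp))
    cov1 <- if (!is.null(dat$cov_raw)) {
      build_covariates(dat$cov_raw, 1L, manifest$women_label, manifest$threat_label)
    } else {
      build_covariates(data.frame(gender = rep(0, nrow(dat$resp$values)),
                                  condition = 0), 1L)
    }
    desc <- stage("descriptives", logf,
                  summarize_descriptives(dat$resp, ind, cov1))
    utils::write.csv(desc$group_stats, fp <- file.path(out, "group_stats.csv"),
                     row.names = FALSE); files <- c(files, fp)
    utils::write.csv(desc$cohens_d, fp <- file.path(out, "cohens_d.csv"),
                     row.names = FALSE); files <- c(files, fp)
    utils::write.csv(desc$item_props, fp <- file.path(out, "item_props.csv"),
                     row.names = FALSE); files <- c(files, fp)
    jsonlite::write_json(list(group_stats = desc$group_stats,
                              cohens_d = desc$cohens_d,
                              proportion_correct = desc$proportion_correct),
                         fp <- file.path(out, "descriptives.json"),
                         digits = NA, auto_unbox = TRUE, dataframe = "rows")
    files <- c(files, fp)

    fits <- list()
    for (m in manifest$models) {
      cov_m <- if (m == 1L) NULL else {
        if (is.null(dat$cov_raw)) stop("model ", m, " requested without covariates")
        dat$cov_raw
      }
      fit <- stage(sprintf("fit_model%d", m), logf, {
        f <- fit_model(dat$resp, ind, cov_m, m, manifest$cfg)
        if (isTRUE(f$escalated)) {
          logf(sprintf("model %d: convergence escalation triggered (burn-in %d)",
                       m, manifest$cfg$escalation_burnin))
        }
        f
      })
      fits[[as.character(m)]] <- fit
      jsonlite::write_json(
        list(model_id = fit$model_id, verdict = fit$verdict,
             escalated = fit$escalated, seed = fit$seed,
             latent_correlation = fit$latent_correlation,
             summary = fit$summary, failures = fit$failures,
             config = unclass(fit$config), metadata = fit$metadata),
        fp <- file.path(out, sprintf("fit_model%d.json", m)),
        digits = NA, auto_unbox = TRUE, dataframe = "rows")
      files <- c(files, fp)
      utils::write.csv(fit$summary,
                       fp <- file.path(out, sprintf("fit_model%d_summary.csv", m)),
                       row.names = FALSE)
      files <- c(files, fp)
    }

    summary_tab <- stage("report", logf, {
      tab <- desc$cohens_d[c("outcome", "d", "ci_lower", "ci_upper")]
      names(tab) <- c("quantity", "estimate", "lower", "upper")
      tab$layer <- "observed (Cohen's d, women - men)"
      if ("2" %in% names(fits)) {
        s <- fits[["2"]]$summary
        lat <- s[s$parameter %in% c("beta_ability", "beta_completion"),
                 c("parameter", "mean", "hpdi_lower", "hpdi_upper")]
        names(lat) <- c("quantity", "estimate", "lower", "upper")
        lat$layer <- "latent (gender coefficient)"
        tab <- rbind(tab, lat)
      }
      tab
    })
    utils::write.csv(summary_tab, fp <- file.path(out, "gap_summary.csv"),
                     row.names = FALSE); files <- c(files, fp)

    if (plots) {
      for (m in names(fits)) {
        # plots are reporting-only; failure to plot never fails the run
        written <- tryCatch(
          plot_diagnostics(fits[[m]]$draws, file.path(out, "plots")),
          error = function(e) character(0))
        files <- c(files, written)
      }
    }

    jsonlite::write_json(
      list(models = manifest$models, seed = manifest$cfg$seed,
           cfg = unclass(manifest$cfg),
           scenario = if (!is.null(manifest$scenario))
             unclass(manifest$scenario)[setdiff(names(manifest$scenario),
                                                c("Sigma", "b"))],
           package_version = as.character(utils::packageVersion("speededirt")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
           outputs = basename(unname(files))),
      file.path(out, "manifest.json"), digits = NA, auto_unbox = TRUE)
    logf("run complete")
    invisible(list(fits = fits, descriptives = desc, out_dir = out,
                   summary = summary_tab))
  }, error = on_fail)
}

#' Refit a model on a person subset
#'
#' Filters persons by a predicate on the covariate table and refits — e.g.
#' the women-only condition contrast (`gender == 1` with Model 3), the
#' simple-effect analysis companion to the full interaction model.
#'
#' @param resp a [response_matrix()].
#' @param ind matching indicators.
#' @param cov a covariate data.frame/table aligned on persons.
#' @param model_id model to fit on the subset.
#' @param cfg an [mcmc_config()].
#' @param filter function taking the covariate data.frame and returning a
#'   logical vector of persons to keep (>= 2 required).
#' @return a `fit_report` with `$subset` describing the filter.
#' @export
subset_fit <- function(resp, ind, cov, model_id, cfg, filter) {
  stopifnot(inherits(resp, "response_matrix"), is.function(filter))
  keep <- filter(as.data.frame(cov))
  if (!is.logical(keep) || length(keep) != nrow(resp$values)) {
    stop("filter must return one logical per person")
  }
  keep[is.na(keep)] <- FALSE
  if (sum(keep) < 2L) stop("subset filter leaves fewer than 2 persons")
  resp_s <- response_matrix(resp$values[keep, , drop = FALSE],
                            item_order = resp$item_order,
                            person_ids = resp$person_ids[keep])
  ind_s <- code_missingness(resp_s)
  cov_s <- as.data.frame(cov)[keep, , drop = FALSE]
  fit <- fit_model(resp_s, ind_s, cov_s, model_id, cfg)
  fit$subset <- sprintf("subset analysis: %d of %d persons retained",
                        sum(keep), length(keep))
  fit
}
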