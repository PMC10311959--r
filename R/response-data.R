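#' Response matrix for a timed test
#'
#' A person-by-item grid of scored responses in administration order. Cells
#' are `1` (correct), `0` (incorrect) or `NA` (no recorded response, whether
#' skipped or not reached). Column order is the administration order of the
#' items; the missingness coding of [code_missingness()] and the linear
#' constraint on completion difficulties are meaningless without it.
#'
#' @param values integer/numeric matrix with cells in `{0, 1, NA}`.
#' @param item_order character vector of item identifiers in administration
#'   order; defaults to the column names of `values`.
#' @param person_ids identifiers for the rows; defaults to row names or
#'   `p1..pN`.
#' @return An object of class `response_matrix`: a list with elements
#'   `values`, `item_order`, `person_ids`.
#' @export
response_matrix <- function(values, item_order = colnames(values),
                            person_ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("response matrix must have at least one person and one item")
  }
  storage.mode(values) <- "integer"
  bad <- !(is.na(values) | values == 0L | values == 1L)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid response cell at row %d, column %d: must be 0, 1 or missing",
                 idx[1L], idx[2L]))
  }
  if (is.null(item_order)) item_order <- paste0("item", seq_len(ncol(values)))
  if (is.null(person_ids)) person_ids <- paste0("p", seq_len(nrow(values)))
  person_ids <- as.character(person_ids)
  if (anyDuplicated(person_ids)) {
    stop("duplicate person id: ", person_ids[duplicated(person_ids)][1L])
  }
  if (length(item_order) != ncol(values)) {
    stop("item_order length does not match number of columns")
  }
  dimnames(values) <- list(person_ids, item_order)
  structure(list(values = values,
                 item_order = as.character(item_order),
                 person_ids = person_ids),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<response_matrix> %d persons x %d items; %.1f%% cells missing\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Read a response matrix from a delimited text file
#'
#' The file must have a header row of item identifiers in administration
#' order. Cells must parse to `0`, `1` or the declared missing token; any
#' other cell is a hard error naming its row and column. A `"9"`-style
#' missing encoding must be declared via `missing_token`, never inferred.
#'
#' @param path path to a delimited text file.
#' @param missing_token string marking a missing response (default `"NA"`).
#' @param delim field delimiter (default `","`).
#' @param id_col optional name of a column holding person identifiers; it is
#'   removed from the item grid. Duplicated ids are an error.
#' @param quiet suppress the ingest log line.
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path, missing_token = "NA", delim = ",",
                                 id_col = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim,
                      colClasses = "character", check.names = FALSE,
                      na.strings = character(0)),
    error = function(e) stop("empty or unreadable response file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (nrow(raw) == 0L || ncol(raw) == 0L) stop("empty response file: ", path)
  ids <- NULL
  if (!is.null(id_col)) {
    if (!id_col %in% names(raw)) stop("id column not found: ", id_col)
    ids <- raw[[id_col]]
    raw <- raw[setdiff(names(raw), id_col)]
  }
  vals <- matrix(NA_integer_, nrow(raw), ncol(raw))
  for (j in seq_along(raw)) {
    cell <- trimws(raw[[j]])
    ok0 <- cell == "0"; ok1 <- cell == "1"; okm <- cell == missing_token
    bad <- which(!(ok0 | ok1 | okm))
    if (length(bad)) {
      stop(sprintf("unparseable cell '%s' at row %d, column '%s' (expected 0, 1 or '%s')",
                   cell[bad[1L]], bad[1L], names(raw)[j], missing_token))
    }
    vals[ok1, j] <- 1L
    vals[ok0, j] <- 0L
  }
  rm <- response_matrix(vals, item_order = names(raw), person_ids = ids)
  if (!quiet) {
    message(sprintf("read %d persons x %d items from %s (%.1f%% missing)",
                    nrow(vals), ncol(vals), path, 100 * mean(is.na(vals))))
  }
  rm
}

#' Write a response matrix to a delimited text file
#'
#' @param resp a [response_matrix()].
#' @param path output path.
#' @param missing_token token for missing cells.
#' @param delim field delimiter.
#' @export
write_response_matrix <- function(resp, path, missing_token = "NA", delim = ",") {
  stopifnot(inherits(resp, "response_matrix"))
  df <- as.data.frame(resp$values)
  for (j in seq_along(df)) {
    col <- as.character(df[[j]])
    col[is.na(col)] <- missing_token
    df[[j]] <- col
  }
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Completion indicators from a response matrix
#'
#' Codes each cell of a response matrix into the missingness indicator used
#' by the completion-factor model: every cell up to (and including) the last
#' observed response of a row gets `1` — this scores intermediate skipped
#' items as attempted; the first item of the terminal run of unanswered
#' items gets `0`; every later item is structurally missing (`NA`) and
#' carries no information. A fully observed row is all `1`s; a row with no
#' observed responses is `0` followed by `NA`s.
#'
#' @param resp a [response_matrix()].
#' @return An object of class `indicator_matrix`: a list with `values`
#'   (N x K matrix of `1`/`0`/`NA`) and the person/item identifiers.
#' @export
code_missingness <- function(resp) {
  stopifnot(inherits(resp, "response_matrix"))
  x <- resp$values
  K <- ncol(x)
  obs <- !is.na(x)
  # index of the last observed response per row; 0 when nothing was answered
  last_obs <- apply(obs, 1L, function(r) if (any(r)) max(which(r)) else 0L)
  col_idx <- matrix(seq_len(K), nrow(x), K, byrow = TRUE)
  d <- matrix(NA_integer_, nrow(x), K)
  d[col_idx <= last_obs] <- 1L
  d[col_idx == last_obs + 1L] <- 0L
  dimnames(d) <- dimnames(x)
  structure(list(values = d,
                 item_order = resp$item_order,
                 person_ids = resp$person_ids),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<indicator_matrix> %d persons x %d items; %d persons stopped early\n",
              nrow(v), ncol(v), sum(rowSums(v == 0L, na.rm = TRUE) > 0L)))
  invisible(x)
}

#' Build a covariate table and model design columns
#'
#' Maps a raw person table to the dummy coding used by the latent regression:
#' gender `1 = women, 0 = men` and condition `1 = stereotype threat,
#' 0 = control`. Multiple control arms are collapsed into `condition = 0`.
#' The design columns depend on the model: Model 1 has none, Model 2 the
#' gender main effect, Model 3 the condition main effect, Model 4 both main
#' effects plus their interaction.
#'
#' @param table data.frame with columns `gender` and `condition` (numeric
#'   dummies or labels) and optionally `subsample`.
#' @param model_id integer in 1..4.
#' @param women_label,threat_label labels mapped to 1 when the columns are
#'   not already numeric dummies; every other label maps to 0 (all control
#'   arms collapse).
#' @return An object of class `covariate_table`: a data.frame with columns
#'   `gender`, `condition`, `subsample`, carrying the model design matrix in
#'   attribute `design` and the model id in attribute `model_id`.
#' @export
build_covariates <- function(table, model_id = 1L,
                             women_label = "women", threat_label = "threat") {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:4) stop("unknown model_id: must be 1, 2, 3 or 4")
  table <- as.data.frame(table)
  if (!all(c("gender", "condition") %in% names(table))) {
    stop("raw table must contain 'gender' and 'condition' columns")
  }
  g <- map_dummy(table$gender, women_label, "gender")
  cnd <- map_dummy(table$condition, threat_label, "condition")
  out <- data.frame(gender = g, condition = cnd,
                    subsample = if ("subsample" %in% names(table))
                      as.character(table$subsample) else "all",
                    stringsAsFactors = FALSE)
  design <- switch(model_id,
    matrix(numeric(0), nrow(out), 0L),
    cbind(gender = g),
    cbind(condition = cnd),
    cbind(gender = g, condition = cnd, gender_x_condition = g * cnd))
  attr(out, "design") <- design
  attr(out, "model_id") <- model_id
  class(out) <- c("covariate_table", "data.frame")
  out
}

# label/numeric column -> {0,1} dummy; 1 is reserved for `one_label` (or a
# pre-coded numeric 1); everything else collapses to 0
map_dummy <- function(x, one_label, what) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("non-binary ", what, " dummy after mapping; values must be 0/1")
    }
    return(as.numeric(x))
  }
  as.numeric(as.character(x) == one_label)
}

#' Extract the design matrix of a covariate table
#' @param cov a [build_covariates()] result.
#' @return numeric matrix (possibly with zero columns).
#' @export
design_matrix <- function(cov) {
  d <- attr(cov, "design")
  if (is.null(d)) stop("covariate table carries no design matrix")
  d
}

#' Descriptive layer: sum scores, group gaps, item curves
#'
#' Computes per-person attempted and correct counts, group means/SDs by
#' gender within each subsample, Cohen's d (women minus men, pooled SD) with
#' a 95% normal-approximation CI for both outcomes, and per-item proportions
#' of attempting/answering correctly by gender. Attempted counts are emitted
#' under two conventions: `attempted` counts indicator 1s (reached items
#' including intermediate skips) and `answered` counts observed responses
#' only; the mean proportion correct is reported both aggregate
#' (sum correct / sum answered) and per-person averaged.
#'
#' @param resp a [response_matrix()].
#' @param ind the matching [code_missingness()] result.
#' @param cov a [build_covariates()] table aligned on persons.
#' @return An object of class `descriptive_summary` (a list): `person`,
#'   `group_stats`, `cohens_d`, `item_props`, `proportion_correct`.
#' @export
summarize_descriptives <- function(resp, ind, cov) {
  stopifnot(inherits(resp, "response_matrix"), inherits(ind, "indicator_matrix"))
  x <- resp$values; d <- ind$values
  if (!identical(dim(x), dim(d)) || nrow(x) != nrow(cov)) {
    stop("response, indicator and covariate tables are not aligned on persons")
  }
  person <- data.frame(
    person_id = resp$person_ids,
    attempted = as.integer(rowSums(d == 1L, na.rm = TRUE)),
    answered  = as.integer(rowSums(!is.na(x))),
    correct   = as.integer(rowSums(x == 1L, na.rm = TRUE)),
    gender    = cov$gender,
    condition = cov$condition,
    subsample = cov$subsample,
    stringsAsFactors = FALSE)

  grp <- function(sub, gender = NULL) {
    rows <- person$subsample %in% sub
    if (!is.null(gender)) rows <- rows & person$gender == gender
    data.frame(n = sum(rows),
               attempted_mean = mean(person$attempted[rows]),
               attempted_sd = stats::sd(person$attempted[rows]),
               correct_mean = mean(person$correct[rows]),
               correct_sd = stats::sd(person$correct[rows]))
  }
  subs <- unique(person$subsample)
  blocks <- list()
  for (s in c(as.list(subs), list(subs))) {
    label <- if (length(s) > 1L) "all" else s
    blocks[[length(blocks) + 1L]] <- cbind(subsample = label, group = "overall", grp(s))
    blocks[[length(blocks) + 1L]] <- cbind(subsample = label, group = "women", grp(s, 1))
    blocks[[length(blocks) + 1L]] <- cbind(subsample = label, group = "men", grp(s, 0))
  }
  group_stats <- do.call(rbind, blocks)

  dtab <- rbind(
    cohens_d(person$attempted[person$gender == 1], person$attempted[person$gender == 0],
             outcome = "attempted"),
    cohens_d(person$correct[person$gender == 1], person$correct[person$gender == 0],
             outcome = "correct"))

  item_props <- do.call(rbind, lapply(seq_len(ncol(x)), function(k) {
    row <- function(gender, label) {
      sel <- cov$gender == gender
      data.frame(item = resp$item_order[k], position = k, gender = label,
                 prop_attempted = mean(d[sel, k] == 1L, na.rm = FALSE),
                 prop_correct = mean(x[sel, k] == 1L & !is.na(x[sel, k])),
                 prop_correct_of_attempted =
                   if (any(sel & !is.na(x[, k]))) mean(x[sel, k][!is.na(x[sel, k])] == 1L)
                   else NA_real_)
    }
    rbind(row(1, "women"), row(0, "men"))
  }))
  item_props$prop_attempted[is.na(item_props$prop_attempted)] <-
    0  # struct-missing cells are unattempted
  ratio <- person$correct / person$answered
  proportion_correct <- list(
    aggregate = sum(person$correct) / sum(person$answered),
    per_person = mean(ratio[person$answered > 0]))
  structure(list(person = person, group_stats = group_stats, cohens_d = dtab,
                 item_props = item_props, proportion_correct = proportion_correct),
            class = "descriptive_summary")
}

#' Cohen's d with a 95% confidence interval
#'
#' Pooled-SD standardized mean difference `x - y` (no small-sample
#' correction), with the normal-approximation standard error
#' `sqrt(1/n1 + 1/n2 + d^2 / (2 (n1 + n2)))`. With the package's gender
#' coding, `x` = women and `y` = men, so negative values favour men.
#'
#' @param x,y numeric vectors for the two groups.
#' @param outcome label copied into the output row.
#' @return one-row data.frame with `d`, `ci_lower`, `ci_upper`, group sizes
#'   and a `defined` flag (FALSE when a group has fewer than 2 members —
#'   flagged, not dropped).
#' @export
cohens_d <- function(x, y, outcome = "outcome") {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    return(data.frame(outcome = outcome, d = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, n1 = n1, n2 = n2, defined = FALSE))
  }
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  d <- (mean(x) - mean(y)) / sp
  se <- sqrt(1 / n1 + 1 / n2 + d^2 / (2 * (n1 + n2)))
  data.frame(outcome = outcome, d = d,
             ci_lower = d - stats::qnorm(0.975) * se,
             ci_upper = d + stats::qnorm(0.975) * se,
             n1 = n1, n2 = n2, defined = TRUE)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient `K/(K-1) * (1 - sum(item variances) /
#' total-score variance)`. Missing responses are handled by the declared
#' scoring rule: `"missing_as_wrong"` recodes `NA` to 0 before computing
#' variances (the usual convention for number-right scoring of speeded
#' tests); `"observed_only"` uses pairwise-complete covariances.
#'
#' @param resp a [response_matrix()].
#' @param scoring_rule `"missing_as_wrong"` or `"observed_only"`.
#' @return numeric alpha with the rule recorded in attribute `scoring_rule`.
#' @export
cronbach_alpha <- function(resp, scoring_rule = c("missing_as_wrong", "observed_only")) {
  stopifnot(inherits(resp, "response_matrix"))
  scoring_rule <- match.arg(scoring_rule)
  x <- resp$values
  if (ncol(x) < 2L) stop("Cronbach's alpha needs at least 2 items")
  K <- ncol(x)
  if (scoring_rule == "missing_as_wrong") {
    x[is.na(x)] <- 0L
    V <- stats::cov(x)
  } else {
    V <- stats::cov(x, use = "pairwise.complete.obs")
    if (anyNA(V)) stop("observed_only scoring: some item pairs share no observations")
  }
  total_var <- sum(V)
  if (!is.finite(total_var) || total_var <= 0) {
    stop("total-score variance is zero; alpha undefined")
  }
  alpha <- K / (K - 1) * (1 - sum(diag(V)) / total_var)
  attr(alpha, "scoring_rule") <- scoring_rule
  alpha
}
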