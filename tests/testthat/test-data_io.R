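test_that("read_response_matrix parses, preserves order, and hard-errors on bad input", {
  f <- write_resp_file("i1,i2\n1,0\n1,NA\nNA,NA")
  expect_message(resp <- read_response_matrix(f), "3 persons x 2 items")
  expect_identical(dim(resp), c(3L, 2L))
  expect_identical(resp$item_order, c("i1", "i2"))
  expect_identical(sum(is.na(resp$values)), 3L)

  expect_error(read_response_matrix(write_resp_file("")), "empty")
  expect_error(read_response_matrix(write_resp_file("i1,i2\n1,2\n0,0")),
               "unparseable cell '2' at row 1, column 'i2'")
  # undeclared "9" encodings must error, never be guessed
  expect_error(read_response_matrix(write_resp_file("i1\n9")), "unparseable")
  expect_silent(read_response_matrix(write_resp_file("i1\n9"),
                                     missing_token = "9", quiet = TRUE))
  expect_error(read_response_matrix(write_resp_file("id,i1\np1,1\np1,0"),
                                    id_col = "id", quiet = TRUE),
               "duplicate person id")
})

test_that("a synthetic study-sized file round-trips through write/read", {
  ds <- small_dataset(N = 794, K = 25, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_response_matrix(ds$response, f)
  back <- read_response_matrix(f, quiet = TRUE)
  expect_identical(dim(back), c(794L, 25L))
  expect_identical(unname(back$values), unname(ds$response$values))
})

test_that("code_missingness applies the indicator rules bit-exactly", {
  SM <- NA_integer_
  cases <- list(
    list(row = c(1, 0, 1, 0, 1, 1), want = c(1, 1, 1, 1, 1, 1)),
    list(row = c(9, 9, 9, 9, 9, 9), want = c(0, SM, SM, SM, SM, SM)),
    # position 3 is an intermediate skip -> scored 1; 5-6 are the terminal run
    list(row = c(1, 0, 9, 1, 9, 9), want = c(1, 1, 1, 1, 0, SM)),
    list(row = c(1, 1, 1, 1, 1, 9), want = c(1, 1, 1, 1, 1, 0)))
  for (cs in cases) {
    got <- code_missingness(rm_from_rows(cs$row))$values[1L, ]
    expect_identical(unname(got), as.integer(cs$want))
  }
})

test_that("indicator invariants hold on random matrices and coding is idempotent", {
  set.seed(42)
  for (i in 1:25) {
    N <- sample(1:12, 1); K <- sample(1:10, 1)
    vals <- matrix(sample(c(0L, 1L, NA), N * K, replace = TRUE), N, K)
    vals[, 1L][is.na(vals[, 1L]) & stats::runif(N) < 0.5] <- 1L
    resp <- response_matrix(vals)
    d1 <- code_missingness(resp)$values
    expect_identical(d1, code_missingness(resp)$values)  # bit-identical rerun
    for (n in seq_len(N)) {
      r <- d1[n, ]
      zeros <- which(!is.na(r) & r == 0L)
      expect_lte(length(zeros), 1L)
      expect_lte(sum(r == 1L, na.rm = TRUE), K)
      if (length(zeros)) {
        # every structurally missing cell lies strictly after the 0, and
        # their count is K minus the 0's position
        expect_identical(sum(is.na(r)), as.integer(K - zeros))
        if (any(is.na(r))) expect_true(all(which(is.na(r)) > zeros))
      } else {
        expect_identical(sum(is.na(r)), 0L)
      }
      # 1s count = cells before the terminal non-reached run
      stop_at <- if (length(zeros)) zeros else K + 1L
      expect_identical(sum(r == 1L, na.rm = TRUE), as.integer(stop_at - 1L))
    }
  }
  # fully observed data => all 1s, no 0-events in the completion channel
  full <- response_matrix(matrix(1L, 4, 5))
  expect_true(all(code_missingness(full)$values == 1L))
})

test_that("build_covariates maps dummies, collapses control arms, builds designs", {
  raw <- data.frame(gender = c("women", "women", "men", "women"),
                    condition = c("control-A", "control-B", "threat", "threat"),
                    subsample = "s1")
  cov <- build_covariates(raw, 4L)
  expect_identical(cov$gender, c(1, 1, 0, 1))
  expect_identical(cov$condition, c(0, 0, 1, 1))  # both control arms -> 0
  d <- design_matrix(cov)
  expect_identical(colnames(d), c("gender", "condition", "gender_x_condition"))
  expect_identical(unname(d[3L, ]), c(0, 1, 0))   # (man, threat), interaction 0
  expect_identical(unname(d[4L, ]), c(1, 1, 1))

  expect_identical(ncol(design_matrix(build_covariates(raw, 1L))), 0L)
  expect_identical(colnames(design_matrix(build_covariates(raw, 2L))), "gender")
  expect_identical(colnames(design_matrix(build_covariates(raw, 3L))), "condition")
  expect_error(build_covariates(raw, 5L), "unknown model_id")
  expect_error(build_covariates(data.frame(gender = c(0, 2), condition = 0), 2L),
               "non-binary")
})

test_that("summarize_descriptives counts, groups and gaps are correct", {
  resp <- rm_from_rows(c(1, 0, 9, 1, 9, 9),  # attempted 4, answered 3, correct 2
                       c(1, 1, 1, 1, 1, 1),
                       c(9, 9, 9, 9, 9, 9),
                       c(0, 1, 9, 9, 9, 9))
  ind <- code_missingness(resp)
  cov <- build_covariates(data.frame(gender = c(1, 1, 0, 0), condition = 0), 1L)
  ds <- summarize_descriptives(resp, ind, cov)
  expect_identical(ds$person$attempted, c(4L, 6L, 0L, 2L))
  expect_identical(ds$person$answered, c(3L, 6L, 0L, 2L))
  expect_identical(ds$person$correct, c(2L, 6L, 0L, 1L))
  expect_true(all(ds$person$correct <= ds$person$answered))
  expect_true(all(ds$person$answered <= ds$person$attempted))
  expect_true(all(ds$cohens_d$defined))
  # both proportion-correct conventions are reported
  expect_equal(ds$proportion_correct$aggregate, 9 / 11)
  expect_equal(ds$proportion_correct$per_person, mean(c(2 / 3, 1, 1 / 2)))
  expect_true(all(ds$item_props$prop_attempted >= 0 & ds$item_props$prop_attempted <= 1))

  # a group with < 2 members is flagged, not dropped
  cov1 <- build_covariates(data.frame(gender = c(1, 1, 1, 0), condition = 0), 1L)
  ds1 <- summarize_descriptives(resp, ind, cov1)
  expect_false(any(ds1$cohens_d$defined))
  expect_true(all(is.na(ds1$cohens_d$d)))
})

test_that("cohens_d matches closed forms and the Monte-Carlo generating gap", {
  expect_equal(cohens_d(rep(c(1, 2), 10), rep(c(1, 2), 10))$d, 0)
  # exact unit separation: construct samples with sample mean/sd exactly (1,1),(2,1)
  z <- scale(rnorm(500))[, 1L]
  expect_equal(cohens_d(z + 1, z + 2)$d, -1)
  set.seed(99)
  d <- cohens_d(rnorm(10000, -0.3, 1), rnorm(10000, 0, 1))
  expect_lt(abs(d$d - (-0.3)), 0.05)
  expect_true(d$ci_lower < d$d && d$d < d$ci_upper)
  # direction convention: women (first argument) minus men
  expect_lt(cohens_d(rnorm(5000, -0.5), rnorm(5000, 0))$d, 0)
})

test_that("cronbach_alpha matches hand value and limiting cases", {
  x <- rbind(c(1, 1, 1), c(1, 1, 0), c(0, 0, 0), c(0, 1, 0))
  # hand: item vars 1/3, 1/4, 1/4; total-score var 5/3
  # alpha = 3/2 * (1 - (1/3 + 1/4 + 1/4) / (5/3)) = 0.75
  a <- cronbach_alpha(response_matrix(x))
  expect_equal(as.numeric(a), 0.75)
  expect_identical(attr(a, "scoring_rule"), "missing_as_wrong")

  same <- matrix(rep(c(1, 0, 1, 1, 0), 4), ncol = 4)
  expect_equal(as.numeric(cronbach_alpha(response_matrix(same))), 1)

  set.seed(7)
  indep <- matrix(rbinom(4000, 1, 0.5), ncol = 4)
  expect_lt(abs(as.numeric(cronbach_alpha(response_matrix(indep)))), 0.1)

  expect_error(cronbach_alpha(response_matrix(matrix(1L, 5, 3))), "variance")
  expect_error(cronbach_alpha(response_matrix(matrix(c(0, 1), 2, 1))), "2 items")
})
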