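complete_analysis <- function(seed = 11, ...) {
  prepare_analysis_data(
    generate_trial(cohort_config(seed = seed, p_followup_missing = 0, ...))
  )
}

masked_analysis <- function(seed = 11, ...) {
  prepare_analysis_data(generate_trial(cohort_config(seed = seed, ...)))
}

test_that("a dataset without missing cells is returned as m identical copies", {
  a <- complete_analysis(seed = 3)
  imp <- impute_trial(a, m = 5, seed = 1)
  expect_length(imp$datasets, 5)
  for (d in imp$datasets) expect_identical(d, a)
  expect_equal(nrow(imp$missing_map), 0)
})

test_that("imputation is reproducible from the master seed", {
  a <- masked_analysis(seed = 7)
  i1 <- impute_trial(a, m = 3, seed = 5)
  i2 <- impute_trial(a, m = 3, seed = 5)
  expect_identical(i1$datasets, i2$datasets)
  i3 <- impute_trial(a, m = 3, seed = 6)
  expect_false(identical(i1$datasets, i3$datasets))
})

test_that("observed cells are never altered and no missing cells remain", {
  a <- masked_analysis(seed = 7)
  imp <- impute_trial(a, m = 4, seed = 2)
  obs_num <- !is.na(a$drinks7_fu)
  for (d in imp$datasets) {
    expect_false(anyNA(d))
    for (col in names(a)) {
      o <- !is.na(a[[col]])
      expect_identical(d[[col]][o], a[[col]][o])
    }
  }
  # imputed hour/score fields respect their logical bounds
  for (d in imp$datasets) {
    expect_true(all(d$absent_hours_fu >= 0))
    expect_true(all(d$drinks7_fu >= 0))
    expect_true(all(d$utility_fu >= -0.594 & d$utility_fu <= 1))
    expect_true(all(d$qols_fu >= 16 & d$qols_fu <= 112))
  }
})

test_that("missingness outside follow-up fields is rejected", {
  a <- masked_analysis(seed = 7)
  a$age[3] <- NA
  expect_error(impute_trial(a, m = 2, seed = 1), "follow-up")
})

test_that("EM non-convergence raises a diagnostic error with a trace", {
  a <- masked_analysis(seed = 7)
  err <- tryCatch(impute_trial(a, m = 2, seed = 1, maxit = 2),
                  error = function(e) e)
  expect_s3_class(err, "netcea_em_nonconvergence")
  expect_true(length(err$trace) >= 1)
})

test_that("the pooled mean recovers the pre-masking complete-data mean", {
  # the same seed yields identical underlying values with and without masking
  truth <- mean(complete_analysis(seed = 19)$utility_fu)
  a <- masked_analysis(seed = 19)
  imp <- impute_trial(a, m = 5, seed = 4)
  est <- vapply(imp$datasets, function(d) mean(d$utility_fu), numeric(1))
  vr <- vapply(imp$datasets, function(d) var(d$utility_fu) / nrow(d),
               numeric(1))
  pooled <- pool_means(est, vr)
  expect_lt(abs(pooled$estimate - truth), 4 * pooled$se)
})

test_that("pooled means are unbiased across repeated mask-impute runs", {
  biases <- vapply(1:20, function(s) {
    truth <- mean(complete_analysis(seed = 100 + s)$drinks7_fu)
    imp <- impute_trial(masked_analysis(seed = 100 + s), m = 5, seed = s)
    mean(vapply(imp$datasets, function(d) mean(d$drinks7_fu), numeric(1))) -
      truth
  }, numeric(1))
  se <- sd(biases) / sqrt(length(biases))
  expect_lt(abs(mean(biases)), 4 * se + 0.5)
})

test_that("Rubin pooling reproduces the hand-computed variance decomposition", {
  p <- pool_means(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$within_var, 1)
  expect_equal(p$between_var, 1)
  expect_equal(p$total_var, 1 + (1 + 1 / 3) * 1)
  # degenerate: identical analyses pool to the single-dataset analysis
  p2 <- pool_means(rep(5, 4), rep(2, 4))
  expect_equal(p2$estimate, 5)
  expect_equal(p2$between_var, 0)
  expect_equal(p2$total_var, p2$within_var)
  # m = 2 arithmetic
  p3 <- pool_means(c(0, 0), c(2, 4))
  expect_equal(p3$estimate, 0)
  expect_equal(p3$within_var, 3)
  # invariant holds on random inputs
  set.seed(8)
  for (i in 1:10) {
    m <- sample(2:8, 1)
    p4 <- pool_means(rnorm(m), runif(m, 0.5, 2))
    expect_equal(p4$total_var, p4$within_var + (1 + 1 / m) * p4$between_var)
    expect_gte(p4$total_var, p4$within_var)
  }
  expect_error(pool_means(1:3, 1:2), "equal length")
  expect_error(pool_means(1, 1), "m >= 2")
})

test_that("appending preserves draw counts and imputation provenance", {
  out <- pool_by_appending(list(tibble::tibble(x = 1:3),
                                tibble::tibble(x = 4:6)))
  expect_equal(nrow(out), 6)
  expect_equal(sort(unique(out$imputation)), c(1, 2))
  big <- pool_by_appending(replicate(5, tibble::tibble(icer = rnorm(1000)),
                                     simplify = FALSE))
  expect_equal(nrow(big), 5000)
  labelled <- pool_by_appending(list(a = 1:2, b = 3:4))
  expect_equal(labelled$imputation, c("a", "a", "b", "b"))
  expect_error(pool_by_appending(list()), "no imputation")
  expect_error(pool_by_appending(list(tibble::tibble(x = numeric(0)))),
               "empty")
})

test_that("imputation sets round-trip through their CSV directory format", {
  imp <- impute_trial(masked_analysis(seed = 23), m = 3, seed = 9)
  dir <- file.path(tempdir(), "impset")
  write_imputation_set(imp, dir)
  back <- read_imputation_set(dir)
  expect_equal(back$m, 3)
  expect_equal(back$seed, 9)
  for (k in 1:3) {
    expect_equal(as.data.frame(back$datasets[[k]]),
                 as.data.frame(imp$datasets[[k]]), tolerance = 1e-10)
  }
  expect_equal(nrow(back$missing_map), nrow(imp$missing_map))
})
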