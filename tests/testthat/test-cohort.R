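test_that("the generator produces the configured trial size and structure", {
  trial <- generate_trial(cohort_config(seed = 1))
  expect_equal(nrow(trial), 136)
  expect_equal(sum(trial$arm == "IT"), 68)
  expect_equal(sum(trial$arm == "IS"), 68)
  # baseline fields complete
  base_cols <- grep("_base$|^age$|^sex$|^arm$|^employed$", names(trial),
                    value = TRUE)
  expect_false(anyNA(trial[base_cols]))
  # non-negative quantities, EQ-5D levels in range
  expect_true(all(trial$drinks7_base >= 0))
  expect_true(all(trial$absent_hours_base >= 0))
  obs <- !is.na(trial$mo_fu)
  expect_true(all(trial$mo_fu[obs] %in% 1:3))
  expect_true(all(trial$mo_base %in% 1:3))
  # missingness only at follow-up
  fu <- grep("_fu$", names(trial), value = TRUE)
  expect_true(anyNA(trial[fu]))
})

test_that("identical seeds reproduce the trial bit for bit, different seeds do not", {
  cfg <- cohort_config(seed = 42)
  expect_identical(generate_trial(cfg), generate_trial(cfg))
  other <- generate_trial(cohort_config(seed = 43))
  expect_false(identical(generate_trial(cfg), other))
})

test_that("zero attrition yields a complete dataset", {
  trial <- generate_trial(cohort_config(p_followup_missing = 0, seed = 5))
  expect_false(anyNA(trial[grep("_fu$", names(trial))]))
})

test_that("masking is applied on top of unchanged underlying values (MAR by construction)", {
  masked <- generate_trial(cohort_config(seed = 11))
  complete <- generate_trial(cohort_config(seed = 11, p_followup_missing = 0))
  obs <- !is.na(masked$drinks7_fu)
  expect_identical(masked$drinks7_fu[obs], complete$drinks7_fu[obs])
  expect_identical(masked$mo_fu[obs], complete$mo_fu[obs])
  expect_identical(masked[grep("_base$", names(masked))],
                   complete[grep("_base$", names(complete))])
})

test_that("out-of-range or non-finite configurations are rejected by name", {
  expect_error(cohort_config(p_female = 1.2), "p_female")
  expect_error(cohort_config(age_sd = -1), "age_sd")
  expect_error(cohort_config(audit_mean = Inf), "audit_mean")
  expect_error(cohort_config(n_per_arm = 1), "n_per_arm")
  expect_error(cohort_config(p_response = c(IT = 0.5, IS = -0.1)),
               "p_response")
})

test_that("attrition ratio follows the completion-fraction arithmetic", {
  flag_trial <- function(n_it, c_it, n_is, c_is) {
    tibble::tibble(
      arm = c(rep("IT", n_it), rep("IS", n_is)),
      complete = c(rep(c(TRUE, FALSE), c(c_it, n_it - c_it)),
                   rep(c(TRUE, FALSE), c(c_is, n_is - c_is)))
    )
  }
  expect_equal(attrition_ratio(flag_trial(68, 50, 68, 50)), 1)
  expect_equal(attrition_ratio(flag_trial(68, 41, 68, 39)), 41 / 39,
               tolerance = 1e-12)
  expect_equal(round(attrition_ratio(flag_trial(68, 41, 68, 39)), 2), 1.05)
  expect_equal(attrition_ratio(flag_trial(68, 34, 68, 17)), 2)
  expect_error(attrition_ratio(flag_trial(68, 10, 68, 0)), "IS arm")
})

test_that("arm moments converge to the configured values at large n", {
  cfg <- cohort_config(n_per_arm = 20000, seed = 9)
  trial <- generate_trial(cfg)
  a <- prepare_analysis_data(trial)
  for (arm in c("IT", "IS")) {
    g <- a[a$arm == arm, ]
    expect_equal(mean(g$age), cfg$age_mean, tolerance = 0.02)
    expect_equal(sd(g$age), cfg$age_sd, tolerance = 0.02)
    expect_equal(mean(g$audit_base), cfg$audit_mean, tolerance = 0.02)
    expect_equal(sd(g$audit_base), cfg$audit_sd, tolerance = 0.02)
    expect_equal(mean(g$drinks_week_base), cfg$drinks_week_mean,
                 tolerance = 0.02)
    expect_equal(sd(g$drinks_week_base), cfg$drinks_week_sd, tolerance = 0.02)
    expect_equal(mean(g$utility_base), cfg$eq5d_base_mean[[arm]],
                 tolerance = 0.02)
    expect_equal(mean(g$utility_fu, na.rm = TRUE), cfg$eq5d_fu_mean[[arm]],
                 tolerance = 0.03)
  }
})

test_that("generated response rates reproduce the configured probability", {
  # pooled empirical IT response over many seeds vs the exact binomial
  # 99% interval at the pooled size
  n_seeds <- 200
  n <- 68
  hits <- 0L
  for (s in seq_len(n_seeds)) {
    trial <- generate_trial(cohort_config(seed = s, p_followup_missing = 0,
                                          eq5d_direct = TRUE))
    a <- prepare_analysis_data(trial)
    resp <- treatment_response(a[a$arm == "IT", ])
    hits <- hits + sum(resp)
  }
  total <- n_seeds * n
  bounds <- qbinom(c(0.005, 0.995), total, 0.53)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("trial tables and configs round-trip through their text formats", {
  trial <- generate_trial(cohort_config(n_per_arm = 10, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_trial(trial, path)
  back <- read_trial(path)
  expect_equal(as.data.frame(back), as.data.frame(trial), tolerance = 1e-12)

  cfg <- cohort_config(n_per_arm = 10, p_followup_missing = 0.25, seed = 77)
  cfg_path <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, cfg_path)
  back_cfg <- read_cohort_config(cfg_path)
  expect_equal(back_cfg$p_followup_missing, 0.25)
  expect_identical(generate_trial(back_cfg), generate_trial(cfg))
})
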