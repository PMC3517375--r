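test_that("resampling degenerate constant data reproduces the constants", {
  inputs <- replicate(5, make_inputs(10), simplify = FALSE)
  d <- bootstrap_cea(inputs, B = 50, seed = 1)
  expect_true(all(d$delta_cost == 100))
  expect_true(all(d$delta_responder == 1))
  expect_true(all(d$delta_cost / d$delta_responder == 100))
})

test_that("five imputations at B = 1000 give 5000 draws", {
  inputs <- replicate(5, make_inputs(5), simplify = FALSE)
  d <- bootstrap_cea(inputs, B = 1000, seed = 1)
  expect_equal(nrow(d), 5000)
  expect_equal(attr(d, "B"), 1000)
  expect_equal(attr(d, "m"), 5)
})

test_that("the bootstrap is deterministic in its seed", {
  a <- prepare_analysis_data(
    generate_trial(cohort_config(n_per_arm = 20, p_followup_missing = 0,
                                 seed = 2))
  )
  d1 <- bootstrap_cea(list(a, a), B = 40, seed = 9)
  d2 <- bootstrap_cea(list(a, a), B = 40, seed = 9)
  expect_identical(tibble::as_tibble(d1), tibble::as_tibble(d2))
  d3 <- bootstrap_cea(list(a, a), B = 40, seed = 10)
  expect_false(identical(tibble::as_tibble(d1), tibble::as_tibble(d3)))
})

test_that("point-estimate ICERs follow the printed ratio arithmetic", {
  expect_equal(icer_point_estimate(845, 0.24), 845 / 0.24)
  expect_equal(round(icer_point_estimate(845, 0.24)), 3521)
  expect_equal(round(icer_point_estimate(845, 0.06)), 14083)
  expect_equal(icer_point_estimate(0, 0.24), 0)
  err <- tryCatch(icer_point_estimate(845, 0), error = function(e) e)
  expect_s3_class(err, "netcea_undefined_icer")
})

test_that("median ICERs use the appended-draw median with zero-effect exclusion", {
  d <- make_draws(delta_cost = c(2, 4, 6), delta_responder = c(1, 1, 1))
  expect_equal(as.numeric(median_icer(d)), 4)
  d2 <- make_draws(delta_cost = c(2, 4, 6, 8), delta_responder = rep(1, 4))
  expect_equal(as.numeric(median_icer(d2)), 5)
  d3 <- make_draws(delta_cost = rep(7, 10), delta_responder = rep(1, 10))
  expect_equal(as.numeric(median_icer(d3)), 7)
  # zero-effect draws are excluded and counted
  d4 <- make_draws(delta_cost = c(2, 4, 6), delta_responder = c(1, 0, 1))
  expect_message(m4 <- median_icer(d4), "zero incremental effect")
  expect_equal(as.numeric(m4), 4)
  expect_equal(attr(m4, "excluded"), 1)
})

test_that("plane quadrants partition the draws with positive-side ties", {
  d <- make_draws(delta_cost = c(1, 2, 3), delta_responder = c(0.1, 0.2, 0.3))
  expect_equal(unlist(quadrant_proportions(d)),
               c(NE = 1, NW = 0, SW = 0, SE = 0))
  d2 <- make_draws(delta_cost = c(1, -1), delta_responder = c(0.1, 0.1))
  expect_equal(unlist(quadrant_proportions(d2)),
               c(NE = 0.5, NW = 0, SW = 0, SE = 0.5))
  # boundary ties go to the positive side and are counted
  d3 <- make_draws(delta_cost = c(0, 1), delta_responder = c(0.1, 0))
  q3 <- quadrant_proportions(d3)
  expect_equal(q3$NE, 1)
  expect_equal(attr(q3, "ties"), 2)
  # proportions always sum to 1
  set.seed(1)
  d4 <- make_draws(delta_cost = rnorm(500), delta_responder = rnorm(500))
  expect_equal(sum(unlist(quadrant_proportions(d4))), 1)
})

test_that("symmetric costs with positive effects split NE/SE evenly", {
  set.seed(42)
  d <- make_draws(delta_cost = rnorm(1000), delta_responder = runif(1000, 0.01, 1))
  q <- quadrant_proportions(d)
  expect_equal(q$NE + q$SE, 1)
  # 99.9% binomial band around 0.5 at n = 1000
  expect_lt(abs(q$NE - 0.5), 3.3 * sqrt(0.25 / 1000))
})

test_that("the CEAC steps at the break-even ratio and matches its limits", {
  d <- make_draws(delta_cost = rep(100, 20), delta_responder = rep(0.1, 20))
  curve <- ceac(d, wtp_grid = c(0, 999, 1001, 5000))
  expect_equal(curve$probability, c(0, 0, 1, 1))
  # CEAC(0) = P(delta_cost < 0), CEAC(inf) = P(delta_effect > 0), exactly
  set.seed(7)
  dm <- make_draws(delta_cost = rnorm(400, 50, 200),
                   delta_responder = rnorm(400, 0.1, 0.3))
  c0 <- ceac(dm, wtp_grid = c(0, 1e9))
  expect_equal(c0$probability[1], mean(dm$delta_cost < 0))
  expect_equal(c0$probability[2], mean(dm$delta_responder > 0))
})

test_that("the CEAC is non-decreasing when no draw has a negative effect", {
  set.seed(8)
  d <- make_draws(delta_cost = rnorm(300, 100, 300),
                  delta_responder = runif(300, 0, 0.5))
  curve <- ceac(d, wtp_grid = seq(0, 20000, 250))
  expect_true(all(diff(curve$probability) >= 0))
})

test_that("quadrants and CEAC agree at the largest NE ratio", {
  set.seed(9)
  d <- make_draws(delta_cost = rnorm(500, 100, 300),
                  delta_responder = runif(500, 0.05, 0.5))
  q <- quadrant_proportions(d)
  ne <- d$delta_responder > 0 & d$delta_cost > 0
  wtp_max <- max(d$delta_cost[ne] / d$delta_responder[ne])
  curve <- ceac(d, wtp_grid = c(0, wtp_max * 1.0001))
  expect_gte(curve$probability[2], q$SE)
})

test_that("indifference-point lookup matches a brute-force grid scan", {
  step <- structure(tibble::tibble(wtp = c(0, 1000, 2000),
                                   probability = c(0, 1, 1)),
                    class = c("ceac_curve", "tbl_df", "tbl", "data.frame"),
                    measure = "responder", n_draws = 10)
  expect_equal(wtp_at_probability(step, 0.5), 1000)
  flat <- structure(tibble::tibble(wtp = c(100, 200), probability = c(0.8, 0.8)),
                    class = class(step), measure = "responder", n_draws = 10)
  expect_equal(wtp_at_probability(flat, 0.5), 100)
  set.seed(10)
  d <- make_draws(delta_cost = rnorm(400, 100, 300),
                  delta_responder = runif(400, 0.05, 0.5))
  grid <- seq(0, 30000, 500)
  curve <- ceac(d, grid)
  scan <- grid[min(which(curve$probability >= 0.5))]
  expect_equal(wtp_at_probability(curve, 0.5), scan)
  expect_error(wtp_at_probability(flat, 0.95), "never reaches")
})

test_that("bootstrap arm means converge to the sample arm means", {
  set.seed(12)
  a <- prepare_analysis_data(
    generate_trial(cohort_config(n_per_arm = 40, p_followup_missing = 0,
                                 seed = 13))
  )
  inp <- cea_inputs(a)
  sample_delta <- mean(inp$societal_total[inp$arm == "IT"]) -
    mean(inp$societal_total[inp$arm == "IS"])
  d <- bootstrap_cea(list(inp), B = 10000, seed = 14)
  expect_equal(mean(d$delta_cost), sample_delta,
               tolerance = 0.01)
})

test_that("the pipeline's mean ICER recovers a calibrated incremental cost and effect", {
  # construct study conditions with analytically known increments:
  # one wage band (43.20: men aged 35-44), full employment, and follow-up
  # productivity confined to IT absenteeism, sized so that
  # E[delta cost] = 845 and E[delta response] = 0.24
  costs <- unit_cost_table()
  d_int <- 3.735 * (50 / 60) * 79.20 + (23.25 + 14.92 + 4.27) - 11.63
  d_time <- (10.33 - 2.43) * 9.18
  rehm <- (0.128 + 0.035) / 0.721
  d_prod_target <- (845 - d_int - d_time) / (1 + rehm)
  p_abs <- 0.5
  m_abs <- d_prod_target / (p_abs * 13 * 43.20 * 0.8)
  hp <- default_hours_params()
  hp$p_report[hp$timepoint == "fu"] <- c(p_abs, 0, 0, 0)
  hp$mean_hours[hp$timepoint == "fu"] <- c(m_abs, 1, 1, 1)
  cfg_for <- function(s) cohort_config(
    p_female = 0, age_mean = 40, age_sd = 1,
    p_employed = c(IT = 1, IS = 1), hours_params = hp,
    p_followup_missing = 0, eq5d_direct = TRUE, seed = s
  )
  reps <- vapply(1:60, function(s) {
    inp <- cea_inputs(prepare_analysis_data(generate_trial(cfg_for(s))),
                      costs)
    c(mean(inp$societal_total[inp$arm == "IT"]) -
        mean(inp$societal_total[inp$arm == "IS"]),
      mean(inp$responder[inp$arm == "IT"]) -
        mean(inp$responder[inp$arm == "IS"]))
  }, numeric(2))
  dc <- mean(reps[1, ]); de <- mean(reps[2, ])
  icer <- icer_point_estimate(dc, de)
  # delta-method Monte-Carlo error of the ratio of replicate means
  se <- abs(icer) * sqrt((sd(reps[1, ]) / sqrt(60) / dc)^2 +
                           (sd(reps[2, ]) / sqrt(60) / de)^2)
  expect_lt(abs(icer - 845 / 0.24), 4 * se)
})

test_that("tidy and glance summarize the distribution consistently", {
  inputs <- replicate(3, make_inputs(8, qaly_it = 0.5, qaly_is = 0.4),
                      simplify = FALSE)
  d <- bootstrap_cea(inputs, B = 20, seed = 5)
  td <- tidy(d)
  expect_equal(nrow(td), 2)
  expect_equal(td$icer_median[td$measure == "responder"], 100)
  expect_equal(td$prop_ne[td$measure == "responder"], 1)
  g <- glance(d)
  expect_equal(g$n_draws, 60)
  expect_equal(g$B, 20)
  cc <- ceac(d, wtp_grid = c(0, 2000))
  expect_s3_class(autoplot(d), "ggplot")
  expect_s3_class(autoplot(cc), "ggplot")
})
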