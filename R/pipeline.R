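#' Configure a full evaluation run
#'
#' Bundles every input of the end-to-end pipeline: the trial source (a
#' [cohort_config()] generator or a patient-level CSV), the unit cost table,
#' outcome definitions, imputation and bootstrap settings, WTP grids,
#' scenario set and output directory.
#'
#' @param cohort A [cohort_config()] (ignored when `input_csv` is given).
#' @param input_csv Optional path to a patient-level trial CSV
#'   (see [read_trial()]).
#' @param costs A [unit_cost_table()].
#' @param criteria A [response_criteria()].
#' @param tariff An [`eq5d_tariff`][dolan_tariff].
#' @param m Number of imputations.
#' @param B Bootstrap replicates per imputation.
#' @param seed Master seed for imputation and bootstrap streams.
#' @param wtp_grid CEAC grid (EUR).
#' @param wtp_responder,wtp_qaly Scenario read-out points.
#' @param scenarios Scenario list.
#' @param horizon Horizon in years.
#' @param output_dir Directory the report bundle is written to; `NULL`
#'   computes everything in memory without writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       input_csv = NULL,
                       costs = unit_cost_table(),
                       criteria = response_criteria(),
                       tariff = dolan_tariff(),
                       m = 5, B = 1000, seed = 1L,
                       wtp_grid = seq(0, 80000, by = 500),
                       wtp_responder = c(4000, 8000, 12000),
                       wtp_qaly = c(10000, 20000, 40000),
                       scenarios = default_scenarios(),
                       horizon = 0.5,
                       output_dir = NULL) {
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    stop("input_csv does not exist: ", input_csv, call. = FALSE)
  }
  if (seed != round(seed)) stop("seed must be an integer", call. = FALSE)
  structure(
    list(cohort = cohort, input_csv = input_csv, costs = costs,
         criteria = criteria, tariff = tariff, m = m, B = B,
         seed = as.integer(seed), wtp_grid = wtp_grid,
         wtp_responder = wtp_responder, wtp_qaly = wtp_qaly,
         scenarios = scenarios, horizon = horizon, output_dir = output_dir),
    class = "run_config"
  )
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cond <- structure(
      class = c("netcea_pipeline_error", "error", "condition"),
      list(message = sprintf("pipeline stage '%s' failed: %s",
                             stage, conditionMessage(e)),
           call = NULL, stage = stage, parent = e)
    )
    stop(cond)
  })
}

#' Run the full economic-evaluation pipeline
#'
#' Generates (or loads) the trial, computes utilities, imputes missing
#' follow-up data, bootstraps the incremental cost-effectiveness
#' distribution, builds acceptability curves, evaluates the scenario grid,
#' and assembles the report bundle: a cohort summary, a pooled cost/effect
#' increment table, the scenario grid, the draw-level and CEAC tables, and a
#' manifest with seeds, settings, tie counts, excluded-draw counts and
#' imputation diagnostics. With `output_dir` set, each table is also written
#' as CSV and the manifest as JSON.
#'
#' @param config A [run_config()].
#' @return An object of class `cea_report` (invisibly a list of tibbles plus
#'   the manifest).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  trial <- pipeline_stage("cohort", {
    if (!is.null(config$input_csv)) read_trial(config$input_csv)
    else generate_trial(config$cohort, config$tariff)
  })
  analysis <- pipeline_stage("outcomes",
                             prepare_analysis_data(trial, config$tariff))
  cohort_summary <- pipeline_stage("cohort_summary",
                                   summarize_cohort(analysis))

  imp <- pipeline_stage("imputation",
                        impute_trial(analysis, m = config$m,
                                     seed = config$seed))

  dist <- pipeline_stage("bootstrap",
                         bootstrap_cea(imp, costs = config$costs,
                                       criteria = config$criteria,
                                       B = config$B, seed = config$seed,
                                       horizon = config$horizon))

  ce_summary <- pipeline_stage("summary",
                               cost_effect_summary(imp, dist, config))
  ceac_resp <- pipeline_stage("ceac", ceac(dist, config$wtp_grid, "responder"))
  ceac_qaly <- pipeline_stage("ceac", ceac(dist, config$wtp_grid, "qaly"))
  grid <- pipeline_stage("scenarios",
                         scenario_grid(dist, config$scenarios,
                                       config$wtp_responder, config$wtp_qaly))

  zero_resp <- sum(dist$delta_responder == 0)
  zero_qaly <- sum(dist$delta_qaly == 0)
  manifest <- list(
    package_version = as.character(utils::packageVersion("netcea")),
    seed = config$seed, m = config$m, B = config$B,
    n_draws = nrow(dist),
    horizon = config$horizon,
    generator = if (is.null(config$input_csv)) "synthetic" else config$input_csv,
    cohort_seed = if (is.null(config$input_csv)) config$cohort$seed else NA,
    imputed_cells = nrow(imp$missing_map),
    em_iterations = imp$em_iterations,
    excluded_zero_effect_draws = list(responder = zero_resp, qaly = zero_qaly),
    boundary_ties = list(
      responder = attr(quadrant_proportions(dist, "responder"), "ties"),
      qaly = attr(quadrant_proportions(dist, "qaly"), "ties")
    )
  )

  report <- structure(
    list(trial = trial, cohort_summary = cohort_summary,
         cost_effect_summary = ce_summary, scenario_grid = grid,
         draws = dist, ceac_responder = ceac_resp, ceac_qaly = ceac_qaly,
         manifest = manifest),
    class = "cea_report"
  )

  if (!is.null(config$output_dir)) {
    pipeline_stage("export", export_report(report, config$output_dir))
  }
  report
}

#' @export
print.cea_report <- function(x, ...) {
  cat("<cea_report>", nrow(x$draws), "draws | seed", x$manifest$seed, "\n")
  print(tidy(x$draws))
  invisible(x)
}

# Table 2 analogue: arm-wise baseline description
summarize_cohort <- function(analysis) {
  dplyr::summarise(
    dplyr::group_by(analysis, .data$arm),
    n = dplyr::n(),
    p_female = mean(.data$sex == "F"),
    age_mean = mean(.data$age), age_sd = stats::sd(.data$age),
    p_employed = mean(.data$employed),
    audit_mean = mean(.data$audit_base), audit_sd = stats::sd(.data$audit_base),
    drinks_week_mean = mean(.data$drinks_week_base),
    drinks_week_sd = stats::sd(.data$drinks_week_base),
    eq5d_mean = mean(.data$utility_base), eq5d_sd = stats::sd(.data$utility_base),
    p_followup_complete = mean(!is.na(.data$drinks7_fu)),
    .groups = "drop"
  )
}

# Table 3 analogue: pooled per-arm component means (Rubin's rules across
# imputations) plus bootstrapped median differences with percentile intervals
cost_effect_summary <- function(imp, dist, config) {
  comps <- c("intervention_therapist", "intervention_software",
             "intervention_total", "participant_time", "absenteeism",
             "presenteeism", "productivity_total", "additional_societal",
             "societal_total", "responder", "qaly", "utility_fu")
  per_imp <- lapply(imp$datasets, function(d) {
    cea_inputs(d, config$costs, config$criteria, horizon = config$horizon)
  })
  pooled <- purrr::map_dfr(comps, function(cmp) {
    purrr::map_dfr(c("IT", "IS"), function(a) {
      est <- vapply(per_imp, function(ci) mean(ci[[cmp]][ci$arm == a]),
                    numeric(1))
      vr <- vapply(per_imp, function(ci) {
        v <- ci[[cmp]][ci$arm == a]
        stats::var(v) / length(v)
      }, numeric(1))
      dplyr::mutate(pool_means(est, vr), component = cmp, arm = a,
                    .before = 1)
    })
  })
  wide <- tidyr::pivot_wider(
    dplyr::select(pooled, "component", "arm", "estimate", "se"),
    names_from = "arm", values_from = c("estimate", "se")
  )
  boot <- purrr::map_dfr(comps, function(cmp) {
    dd <- dist[[if (cmp == "societal_total") "delta_cost"
                else paste0("delta_", cmp)]]
    tibble::tibble(
      component = cmp,
      diff_median = stats::median(dd),
      diff_low = unname(stats::quantile(dd, 0.025)),
      diff_high = unname(stats::quantile(dd, 0.975))
    )
  })
  dplyr::left_join(wide, boot, by = "component")
}

#' Write a report bundle to disk
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "cea_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$cohort_summary, file.path(dir, "cohort_summary.csv"))
  readr::write_csv(report$cost_effect_summary,
                   file.path(dir, "cost_effect_summary.csv"))
  readr::write_csv(report$scenario_grid, file.path(dir, "scenario_grid.csv"))
  readr::write_csv(tibble::as_tibble(report$draws), file.path(dir, "draws.csv"))
  readr::write_csv(tibble::as_tibble(report$ceac_responder),
                   file.path(dir, "ceac_responder.csv"))
  readr::write_csv(tibble::as_tibble(report$ceac_qaly),
                   file.path(dir, "ceac_qaly.csv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Round costs for presentation
#'
#' Internal computation is at full precision; reports round to whole euros
#' (summary-table style) or two decimals (unit-cost style).
#'
#' @param x Numeric euros.
#' @param style `"whole"` or `"cents"`.
#' @return Rounded numeric.
#' @export
round_euro <- function(x, style = c("whole", "cents")) {
  style <- match.arg(style)
  round(x, if (style == "whole") 0 else 2)
}
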