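#' Unit cost table for the economic evaluation
#'
#' Collects every price and costing parameter used by the pipeline, all in
#' euros of the 2010 reference year over a 6-month horizon: therapist labour
#' (EUR 79.20/h, 40 min of chat contact plus 10 min of supervision and
#' administration per session), fixed per-participant software/ICT/overhead
#' components by arm, the leisure-time rate used to value participants' own
#' time investment (EUR 9.18/h), a sex- and age-band gross wage table for the
#' human-capital valuation of SF-HLQ absenteeism and presenteeism hours
#' (bounded by EUR 22.21-52.91/h), the labour-reserve elasticity (0.8), the
#' macro-level societal cost shares (productivity 72.1%, additional health
#' care 12.8%, law enforcement 3.5%), and HICP inflation factors for indexing
#' historical amounts to 2010.
#'
#' @param therapist_rate Therapist labour cost, EUR per hour.
#' @param contact_min,admin_min Minutes of chat contact and of
#'   supervision/administration per therapy session.
#' @param leisure_rate Value of participant leisure time, EUR per hour.
#' @param software_dev,ict_service,overhead Named numeric vectors `c(IT = , IS = )`:
#'   fixed per-participant components in EUR, charged to every randomized
#'   participant regardless of uptake.
#' @param wage_table Tibble with columns `sex`, `age_min`, `age_max`, `wage`
#'   (EUR per hour). Defaults to the bundled 10-year-band table.
#' @param elasticity Fraction of absent production genuinely lost after firms'
#'   internal labour reserves compensate (dimensionless, in (0, 1]).
#' @param elasticity_absenteeism,elasticity_presenteeism Whether the
#'   elasticity is applied to each productivity component. Both default to
#'   `TRUE` (uniform application; see the methods vignette).
#' @param societal_shares Named proportions `productivity`, `healthcare`,
#'   `law_enforcement` of overall alcohol-attributable societal costs.
#' @param hicp_factors Tibble with columns `year`, `factor_to_2010`.
#' @param horizon Analytic horizon in years (0.5 = 6 months).
#' @param recall_weeks SF-HLQ productivity recall window in weeks.
#' @return An object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(therapist_rate = 79.20,
                            contact_min = 40,
                            admin_min = 10,
                            leisure_rate = 9.18,
                            software_dev = c(IT = 23.25, IS = 4.87),
                            ict_service = c(IT = 14.92, IS = 2.49),
                            overhead = c(IT = 4.27, IS = 4.27),
                            wage_table = NULL,
                            elasticity = 0.8,
                            elasticity_absenteeism = TRUE,
                            elasticity_presenteeism = TRUE,
                            societal_shares = c(productivity = 0.721,
                                                healthcare = 0.128,
                                                law_enforcement = 0.035),
                            hicp_factors = NULL,
                            horizon = 0.5,
                            recall_weeks = 2) {
  if (is.null(wage_table)) {
    wage_table <- readr::read_csv(
      system.file("extdata", "wage_table.csv", package = "netcea", mustWork = TRUE),
      show_col_types = FALSE
    )
  }
  if (is.null(hicp_factors)) {
    hicp_factors <- readr::read_csv(
      system.file("extdata", "hicp_factors.csv", package = "netcea", mustWork = TRUE),
      show_col_types = FALSE
    )
  }
  rates <- c(therapist_rate, leisure_rate, software_dev, ict_service, overhead,
             wage_table$wage, contact_min, admin_min)
  if (!all(is.finite(rates)) || any(rates < 0)) {
    stop("all rates, prices and minutes must be finite and non-negative",
         call. = FALSE)
  }
  if (!(elasticity > 0 && elasticity <= 1)) {
    stop("elasticity must lie in (0, 1]", call. = FALSE)
  }
  if (!all(societal_shares > 0 & societal_shares < 1)) {
    stop("societal shares must each lie in (0, 1)", call. = FALSE)
  }
  if (horizon <= 0 || recall_weeks <= 0) {
    stop("horizon and recall window must be positive", call. = FALSE)
  }
  structure(
    list(
      therapist_rate = therapist_rate,
      contact_min = contact_min,
      admin_min = admin_min,
      leisure_rate = leisure_rate,
      software_dev = software_dev,
      ict_service = ict_service,
      overhead = overhead,
      wage_table = wage_table,
      elasticity = elasticity,
      elasticity_absenteeism = elasticity_absenteeism,
      elasticity_presenteeism = elasticity_presenteeism,
      societal_shares = societal_shares,
      hicp_factors = hicp_factors,
      horizon = horizon,
      recall_weeks = recall_weeks
    ),
    class = "unit_cost_table"
  )
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("<unit_cost_table> therapist", x$therapist_rate, "EUR/h |",
      "leisure", x$leisure_rate, "EUR/h |",
      "elasticity", x$elasticity, "|",
      "horizon", x$horizon, "y\n")
  invisible(x)
}

#' Index a historical amount to the 2010 reference year
#'
#' Applies the Harmonized Index of Consumer Prices correction factor for the
#' calendar year in which a cost was recorded.
#'
#' @param amount Amount in EUR of `year`.
#' @param year Calendar year the amount was recorded in.
#' @param costs A [unit_cost_table()].
#' @return Amount in 2010 EUR.
#' @export
index_to_reference_year <- function(amount, year, costs = unit_cost_table()) {
  hit <- match(year, costs$hicp_factors$year)
  if (anyNA(hit)) {
    stop("no HICP factor for year(s): ",
         paste(unique(year[is.na(hit)]), collapse = ", "), call. = FALSE)
  }
  amount * costs$hicp_factors$factor_to_2010[hit]
}

#' Intervention cost per participant
#'
#' Therapist labour (chat contact plus per-session supervision/administration,
#' IT arm only) plus the fixed software-development, ICT-service and overhead
#' components. The fixed components are charged per randomized participant
#' (intention-to-treat), including non-starters.
#'
#' @param contact_hours,admin_hours Therapist chat-contact and administration
#'   hours for the participant (0 for the self-help arm).
#' @param arm `"IT"` or `"IS"` (vectorized).
#' @param costs A [unit_cost_table()].
#' @return Cost in EUR per participant.
#' @export
#' @examples
#' intervention_cost(2.49, 0.55, "IT") # 283.21
#' intervention_cost(0, 0, "IS")       # 11.63
intervention_cost <- function(contact_hours, admin_hours, arm,
                              costs = unit_cost_table()) {
  if (any(contact_hours < 0 | admin_hours < 0, na.rm = TRUE)) {
    stop("uptake hours must be non-negative", call. = FALSE)
  }
  arm <- match.arg_vec(arm)
  fixed <- costs$software_dev[arm] + costs$ict_service[arm] + costs$overhead[arm]
  therapist <- ifelse(arm == "IT",
                      (contact_hours + admin_hours) * costs$therapist_rate, 0)
  unname(therapist + fixed)
}

# vectorized arm validation
match.arg_vec <- function(arm) {
  arm <- as.character(arm)
  if (!all(arm %in% c("IT", "IS"))) {
    stop("arm must be 'IT' or 'IS'", call. = FALSE)
  }
  arm
}

#' Participant time-investment cost
#'
#' Hours a participant invests in the intervention (sessions, homework, chat
#' time) valued as leisure time, on the assumption that therapy is not
#' received during office hours.
#'
#' @param hours Invested hours over the horizon.
#' @param costs A [unit_cost_table()].
#' @return Cost in EUR.
#' @export
#' @examples
#' participant_time_cost(10.33) # 94.83
participant_time_cost <- function(hours, costs = unit_cost_table()) {
  if (any(hours < 0, na.rm = TRUE)) stop("hours must be non-negative", call. = FALSE)
  hours * costs$leisure_rate
}

#' Gross hourly wage by sex and age band
#'
#' @param sex `"F"` or `"M"` (vectorized).
#' @param age Age in years.
#' @param costs A [unit_cost_table()].
#' @return Wage in EUR per hour.
#' @export
wage_rate <- function(sex, age, costs = unit_cost_table()) {
  wt <- costs$wage_table
  out <- purrr::map2_dbl(as.character(sex), age, function(s, a) {
    i <- which(wt$sex == s & a >= wt$age_min & a < wt$age_max + 1)
    if (length(i) != 1L) {
      stop(sprintf("no wage entry for sex %s, age %.0f", s, a), call. = FALSE)
    }
    wt$wage[i]
  })
  out
}

#' Productivity costs from SF-HLQ hours (human-capital approach)
#'
#' Absenteeism and presenteeism hours reported over the 2-week SF-HLQ recall
#' window are extrapolated linearly to the 6-month horizon (factor 26/2 = 13
#' under the defaults), multiplied by the participant's sex- and age-specific
#' gross wage and by the 0.8 labour-reserve elasticity. Participants without
#' paid employment incur no productivity cost.
#'
#' @param absent_hours,present_hours Hours over the recall window. Set
#'   `extrapolate = FALSE` if hours are already on the horizon scale.
#' @param sex,age,employed Participant covariates (vectorized).
#' @param costs A [unit_cost_table()].
#' @param extrapolate Apply the recall-window-to-horizon factor (default TRUE).
#' @return A tibble with columns `absenteeism` and `presenteeism` (EUR).
#' @export
productivity_cost <- function(absent_hours, present_hours, sex, age, employed,
                              costs = unit_cost_table(), extrapolate = TRUE) {
  if (any(c(absent_hours, present_hours) < 0, na.rm = TRUE)) {
    stop("hours must be non-negative", call. = FALSE)
  }
  fac <- if (extrapolate) (costs$horizon * 52) / costs$recall_weeks else 1
  wage <- wage_rate(sex, age, costs)
  e_abs <- if (costs$elasticity_absenteeism) costs$elasticity else 1
  e_pre <- if (costs$elasticity_presenteeism) costs$elasticity else 1
  emp <- as.numeric(employed)
  tibble::tibble(
    absenteeism = emp * absent_hours * fac * wage * e_abs,
    presenteeism = emp * present_hours * fac * wage * e_pre
  )
}

#' Additional societal costs via the macro cost-share ratio
#'
#' In high-income countries productivity losses make up 72.1% of overall
#' alcohol-attributable societal costs; additional health-care resource use
#' (12.8%) and law enforcement (3.5%) are imputed proportionally from the
#' measured productivity costs: `productivity * (0.128 + 0.035) / 0.721`.
#'
#' @param productivity_total Per-participant productivity cost, EUR.
#' @param costs A [unit_cost_table()].
#' @return Additional societal cost in EUR.
#' @export
#' @examples
#' additional_societal_cost(1331) # ~301
additional_societal_cost <- function(productivity_total,
                                     costs = unit_cost_table()) {
  s <- costs$societal_shares
  ratio <- (s[["healthcare"]] + s[["law_enforcement"]]) / s[["productivity"]]
  productivity_total * ratio
}

#' Per-participant cost breakdown
#'
#' Builds the full component cost table (one row per participant) from
#' resource-use quantities, under the societal perspective (intervention +
#' participant time + productivity + additional societal costs) or the
#' health-care-provider perspective (intervention costs only; all other
#' components zero).
#'
#' Expects the analysis columns produced by [generate_trial()] /
#' [prepare_analysis_data()]: `id`, `arm`, `sex`, `age`, `employed`,
#' `contact_hours`, `admin_hours`, `time_invested_hours`, and the
#' timepoint-specific SF-HLQ columns `absent_hours_<tp>`,
#' `present_hours_<tp>`.
#'
#' @param data Participant-level data frame.
#' @param costs A [unit_cost_table()].
#' @param perspective `"societal"` or `"provider"`.
#' @param timepoint `"fu"` (6-month follow-up, default) or `"base"`.
#' @return A tibble, one row per participant, with columns
#'   `intervention_therapist`, `intervention_software`, `intervention_total`,
#'   `participant_time`, `absenteeism`, `presenteeism`, `productivity_total`,
#'   `additional_societal`, `societal_total`.
#' @export
cost_breakdown <- function(data, costs = unit_cost_table(),
                           perspective = c("societal", "provider"),
                           timepoint = c("fu", "base")) {
  perspective <- match.arg(perspective)
  timepoint <- match.arg(timepoint)
  abs_col <- paste0("absent_hours_", timepoint)
  pre_col <- paste0("present_hours_", timepoint)
  need <- c("id", "arm", "sex", "age", "employed", "contact_hours",
            "admin_hours", "time_invested_hours", abs_col, pre_col)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("cost_breakdown: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  arm <- match.arg_vec(data$arm)
  fixed <- costs$software_dev[arm] + costs$ict_service[arm] + costs$overhead[arm]
  therapist <- ifelse(arm == "IT",
                      (data$contact_hours + data$admin_hours) * costs$therapist_rate,
                      0)
  time_cost <- participant_time_cost(data$time_invested_hours, costs)
  prod <- productivity_cost(data[[abs_col]], data[[pre_col]],
                            data$sex, data$age, data$employed, costs)
  prod_total <- prod$absenteeism + prod$presenteeism
  extra <- additional_societal_cost(prod_total, costs)
  if (perspective == "provider") {
    time_cost <- prod$absenteeism <- prod$presenteeism <- prod_total <- extra <- 0
  }
  tibble::tibble(
    id = data$id,
    arm = arm,
    intervention_therapist = unname(therapist),
    intervention_software = unname(fixed),
    intervention_total = unname(therapist + fixed),
    participant_time = unname(time_cost),
    absenteeism = unname(prod$absenteeism * rep(1, nrow(data))),
    presenteeism = unname(prod$presenteeism * rep(1, nrow(data))),
    productivity_total = unname(prod_total * rep(1, nrow(data))),
    additional_societal = unname(extra * rep(1, nrow(data))),
    societal_total = unname(therapist + fixed + time_cost + prod_total + extra)
  )
}
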