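#' Composite treatment-response criteria
#'
#' The clinical response outcome combines a consumption boundary with a
#' no-deterioration clause: weekly alcohol consumption (drinks in the last 7
#' days) within the British Medical Association limits — no more than 14
#' standard units for women or 21 for men — and no deterioration of more than
#' 10% relative to baseline on any of the AUDIT, QOLS, or BSI Global Severity
#' Index. AUDIT and BSI-GSI are higher-is-worse; QOLS is higher-is-better.
#'
#' @param max_units_female,max_units_male Weekly standard-drink limits.
#' @param max_deterioration Relative deterioration that precludes response
#'   (strictly-greater-than comparison; exactly 10% still counts as response).
#' @return An object of class `response_criteria`.
#' @export
response_criteria <- function(max_units_female = 14,
                              max_units_male = 21,
                              max_deterioration = 0.10) {
  if (max_units_female <= 0 || max_units_male <= 0) {
    stop("consumption limits must be positive", call. = FALSE)
  }
  if (!(max_deterioration > 0 && max_deterioration < 1)) {
    stop("max_deterioration must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(max_units_female = max_units_female,
         max_units_male = max_units_male,
         max_deterioration = max_deterioration),
    class = "response_criteria"
  )
}

# Relative deterioration of a follow-up score against baseline.
# direction +1: higher is worse (AUDIT, BSI); -1: higher is better (QOLS).
# A zero baseline makes any worsening count as deterioration beyond any
# threshold (documented convention).
relative_deterioration <- function(base, fu, direction) {
  worsening <- direction * (fu - base)
  ifelse(base == 0, ifelse(worsening > 0, Inf, 0), worsening / abs(base))
}

#' Composite treatment response
#'
#' @param data Participant-level data frame with columns `sex`,
#'   `drinks7_fu`, and baseline/follow-up instrument scores `audit_base`,
#'   `audit_fu`, `qols_base`, `qols_fu`, `bsi_base`, `bsi_fu`.
#' @param criteria A [response_criteria()] object.
#' @return Logical vector, one element per row; `NA` where any required
#'   follow-up input is missing (to be resolved upstream by imputation, never
#'   silently treated as non-response).
#' @export
treatment_response <- function(data, criteria = response_criteria()) {
  stopifnot(inherits(criteria, "response_criteria"))
  need <- c("sex", "drinks7_fu", "audit_base", "audit_fu",
            "qols_base", "qols_fu", "bsi_base", "bsi_fu")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("treatment_response: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  limit <- ifelse(data$sex == "F", criteria$max_units_female,
                  criteria$max_units_male)
  within_limit <- data$drinks7_fu <= limit
  det <- pmax(
    relative_deterioration(data$audit_base, data$audit_fu, +1),
    relative_deterioration(data$bsi_base, data$bsi_fu, +1),
    relative_deterioration(data$qols_base, data$qols_fu, -1)
  )
  within_limit & (det <= criteria$max_deterioration)
}

#' Quality-adjusted life-years over the trial horizon
#'
#' The default (`method = "endpoint"`) follows the trial's own accrual
#' arithmetic: the follow-up utility is carried over the whole horizon, so the
#' between-arm QALY increment equals the mean follow-up utility difference
#' times the horizon (e.g. 0.12 x 0.5 = 0.06). `method = "auc"` offers the
#' trapezoidal area-under-curve alternative instead (off by default).
#'
#' @param u_base,u_fu Baseline and follow-up utilities.
#' @param horizon Horizon in years (default 0.5).
#' @param method `"endpoint"` (default) or `"auc"`.
#' @return Per-participant QALYs.
#' @export
#' @examples
#' qaly(0.8, 0.9)          # 0.45 QALY over half a year
qaly <- function(u_base, u_fu, horizon = 0.5,
                 method = c("endpoint", "auc")) {
  method <- match.arg(method)
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  switch(method,
         endpoint = u_fu * horizon,
         auc = (u_base + u_fu) / 2 * horizon)
}

#' Incremental QALYs from a follow-up utility difference
#'
#' @param utility_difference Mean follow-up utility difference between arms.
#' @param horizon Horizon in years.
#' @return Incremental QALYs.
#' @export
#' @examples
#' incremental_qaly(0.12) # 0.06
incremental_qaly <- function(utility_difference, horizon = 0.5) {
  utility_difference * horizon
}

#' Attach effect outcomes to an analysis table
#'
#' Adds `responder` (composite treatment response) and `qaly` columns.
#'
#' @param data Analysis tibble (see [prepare_analysis_data()]).
#' @param criteria A [response_criteria()].
#' @param horizon,method Passed to [qaly()].
#' @return `data` with `responder` and `qaly` columns appended.
#' @export
add_outcomes <- function(data, criteria = response_criteria(),
                         horizon = 0.5, method = "endpoint") {
  dplyr::mutate(
    data,
    responder = treatment_response(data, criteria),
    qaly = qaly(.data$utility_base, .data$utility_fu, horizon, method)
  )
}
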