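# Build a per-participant cost/effect inputs table directly (bypassing the
# generator) for bootstrap tests with known, often degenerate, values.
make_inputs <- function(n_per_arm,
                        cost_it = 100, cost_is = 0,
                        resp_it = 1, resp_is = 0,
                        qaly_it = 0.5, qaly_is = 0.4,
                        intervention_it = cost_it, intervention_is = cost_is) {
  one_arm <- function(arm, cost, resp, q, interv) {
    tibble::tibble(
      id = seq_len(n_per_arm), arm = arm,
      intervention_therapist = interv, intervention_software = 0,
      intervention_total = interv,
      participant_time = 0,
      absenteeism = cost - interv, presenteeism = 0,
      productivity_total = cost - interv,
      additional_societal = 0,
      societal_total = cost,
      responder = resp, qaly = q, utility_fu = q / 0.5
    )
  }
  dplyr::bind_rows(
    one_arm("IT", cost_it, resp_it, qaly_it, intervention_it),
    one_arm("IS", cost_is, resp_is, qaly_is, intervention_is)
  )
}

# Minimal icer-distribution-like table for the plane/curve operations, which
# only index the delta_* columns.
make_draws <- function(delta_cost, delta_responder,
                       delta_qaly = delta_responder / 4,
                       delta_intervention_total = 0,
                       delta_participant_time = 0,
                       delta_productivity_total = delta_cost,
                       delta_additional_societal = 0) {
  tibble::tibble(
    delta_cost = delta_cost,
    delta_responder = delta_responder,
    delta_qaly = delta_qaly,
    delta_intervention_total = delta_intervention_total,
    delta_participant_time = delta_participant_time,
    delta_productivity_total = delta_productivity_total,
    delta_additional_societal = delta_additional_societal
  )
}

# A unit cost table with a single flat wage band, convenient for arithmetic
# oracles.
flat_wage_costs <- function(wage = 30, ...) {
  unit_cost_table(
    wage_table = tibble::tibble(sex = c("F", "M"), age_min = 18,
                                age_max = 120, wage = wage),
    ...
  )
}

# One-row analysis table with fully specified fields, for outcome/cost tests.
one_participant <- function(arm = "IT", sex = "F", age = 40, employed = TRUE,
                            contact_hours = 0, admin_hours = 0,
                            time_invested_hours = 0,
                            audit_base = 20, audit_fu = 20,
                            qols_base = 80, qols_fu = 80,
                            bsi_base = 1, bsi_fu = 1,
                            drinks7_base = 30, drinks7_fu = 10,
                            utility_base = 0.8, utility_fu = 0.9,
                            absent_hours_base = 0, absent_hours_fu = 0,
                            present_hours_base = 0, present_hours_fu = 0) {
  tibble::tibble(
    id = 1L, arm = arm, sex = sex, age = age, employed = employed,
    contact_hours = contact_hours, admin_hours = admin_hours,
    time_invested_hours = time_invested_hours,
    audit_base = audit_base, audit_fu = audit_fu,
    qols_base = qols_base, qols_fu = qols_fu,
    bsi_base = bsi_base, bsi_fu = bsi_fu,
    drinks7_base = drinks7_base, drinks7_fu = drinks7_fu,
    utility_base = utility_base, utility_fu = utility_fu,
    absent_hours_base = absent_hours_base, absent_hours_fu = absent_hours_fu,
    present_hours_base = present_hours_base,
    present_hours_fu = present_hours_fu
  )
}
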