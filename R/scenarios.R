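#' Define a costing scenario
#'
#' A scenario is a perspective (societal or health-care provider) plus
#' multiplicative scale factors on the two dominant cost drivers:
#' intervention costs and productivity costs. The productivity factor is
#' applied before the macro cost-share ratio, so the derived additional
#' societal costs scale coherently with productivity. Participant time costs
#' are driven by neither factor by default (configurable via `time_scale`).
#'
#' @param name Scenario label.
#' @param perspective `"societal"` or `"provider"`.
#' @param intervention_scale,productivity_scale,time_scale Positive
#'   multipliers.
#' @return An object of class `cea_scenario`.
#' @export
scenario <- function(name, perspective = c("societal", "provider"),
                     intervention_scale = 1, productivity_scale = 1,
                     time_scale = 1) {
  perspective <- match.arg(perspective)
  scales <- c(intervention_scale, productivity_scale, time_scale)
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    stop("scenario scale factors must be positive", call. = FALSE)
  }
  structure(
    list(name = name, perspective = perspective,
         intervention_scale = intervention_scale,
         productivity_scale = productivity_scale,
         time_scale = time_scale),
    class = "cea_scenario"
  )
}

#' The default scenario set
#'
#' Base case (societal), health-care-provider perspective, and the
#' intervention/productivity cost drivers raised and lowered independently
#' and jointly by 40% and 60%.
#'
#' @return Named list of [scenario()] objects.
#' @export
default_scenarios <- function() {
  specs <- list(
    scenario("base case", "societal"),
    scenario("provider perspective", "provider"),
    scenario("I -40%", intervention_scale = 0.6),
    scenario("I +40%", intervention_scale = 1.4),
    scenario("P -40%", productivity_scale = 0.6),
    scenario("P +40%", productivity_scale = 1.4),
    scenario("I and P -40%", intervention_scale = 0.6, productivity_scale = 0.6),
    scenario("I and P +40%", intervention_scale = 1.4, productivity_scale = 1.4),
    scenario("I -60%", intervention_scale = 0.4),
    scenario("I +60%", intervention_scale = 1.6),
    scenario("P -60%", productivity_scale = 0.4),
    scenario("P +60%", productivity_scale = 1.6),
    scenario("I and P -60%", intervention_scale = 0.4, productivity_scale = 0.4),
    scenario("I and P +60%", intervention_scale = 1.6, productivity_scale = 1.6)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Apply a scenario to a per-participant cost breakdown
#'
#' Intervention components are multiplied by `intervention_scale`;
#' productivity components (and hence the derived additional societal costs)
#' by `productivity_scale`; totals are recomputed so the additivity
#' invariants continue to hold. The provider perspective zeroes every
#' non-intervention component.
#'
#' @param breakdowns A [cost_breakdown()] (or [cea_inputs()]) tibble.
#' @param scen A [scenario()].
#' @return The modified tibble.
#' @export
apply_scenario <- function(breakdowns, scen) {
  stopifnot(inherits(scen, "cea_scenario"))
  b <- breakdowns
  iscale <- scen$intervention_scale
  pscale <- scen$productivity_scale
  b$intervention_therapist <- b$intervention_therapist * iscale
  b$intervention_software <- b$intervention_software * iscale
  b$intervention_total <- b$intervention_total * iscale
  b$participant_time <- b$participant_time * scen$time_scale
  b$absenteeism <- b$absenteeism * pscale
  b$presenteeism <- b$presenteeism * pscale
  b$productivity_total <- b$productivity_total * pscale
  b$additional_societal <- b$additional_societal * pscale
  if (scen$perspective == "provider") {
    b$participant_time <- b$absenteeism <- b$presenteeism <- 0
    b$productivity_total <- b$additional_societal <- rep(0, nrow(b))
  }
  b$societal_total <- b$intervention_total + b$participant_time +
    b$productivity_total + b$additional_societal
  b
}

# scenario-adjusted incremental cost, computed algebraically from the
# component-level deltas recorded per bootstrap draw (common random numbers
# across scenarios by construction)
scenario_delta_cost <- function(dist, scen) {
  dc <- scen$intervention_scale * dist$delta_intervention_total
  if (scen$perspective == "provider") return(dc)
  dc +
    scen$time_scale * dist$delta_participant_time +
    scen$productivity_scale *
      (dist$delta_productivity_total + dist$delta_additional_societal)
}

#' Scenario sensitivity grid
#'
#' Re-evaluates the bootstrapped cost-effectiveness summary under each
#' costing scenario. Because every scenario is an algebraic reweighting of
#' the same component-level bootstrap draws, all scenarios share identical
#' resampling (common random numbers): the identity scenario reproduces the
#' base case exactly, and between-scenario differences are purely
#' scenario-driven.
#'
#' @param dist An [bootstrap_cea()] `icer_distribution` (societal
#'   perspective, so all components are available for reweighting).
#' @param scenarios List of [scenario()] objects (default
#'   [default_scenarios()]).
#' @param wtp_responder,wtp_qaly WTP read-out points, EUR per responder and
#'   per QALY.
#' @return A tibble with one row per scenario x effect measure: median
#'   incremental cost and effect, median ICER (all-draw and NE-quadrant),
#'   95% percentile interval, quadrant proportions, and the CEAC probability
#'   at each read-out point (columns `wtp_<value>`).
#' @export
scenario_grid <- function(dist, scenarios = default_scenarios(),
                          wtp_responder = c(4000, 8000, 12000),
                          wtp_qaly = c(10000, 20000, 40000)) {
  if (!length(scenarios)) stop("scenarios must be non-empty", call. = FALSE)
  purrr::map_dfr(scenarios, function(scen) {
    d <- dist
    d$delta_cost <- scenario_delta_cost(dist, scen)
    purrr::map_dfr(c("responder", "qaly"), function(ms) {
      de <- d[[effect_column(ms)]]
      keep <- de != 0
      ratios <- d$delta_cost[keep] / de[keep]
      q <- quadrant_proportions(d, ms)
      wtps <- if (ms == "responder") wtp_responder else wtp_qaly
      probs <- vapply(wtps, function(w) mean(w * de - d$delta_cost > 0),
                      numeric(1))
      names(probs) <- paste0("wtp_", wtps)
      ne <- de > 0 & d$delta_cost > 0
      dplyr::bind_cols(
        tibble::tibble(
          scenario = scen$name,
          perspective = scen$perspective,
          intervention_scale = scen$intervention_scale,
          productivity_scale = scen$productivity_scale,
          measure = ms,
          delta_cost_median = stats::median(d$delta_cost),
          delta_effect_median = stats::median(de),
          icer_median = stats::median(ratios),
          icer_median_ne = stats::median(d$delta_cost[ne] / de[ne]),
          icer_low = unname(stats::quantile(ratios, 0.025)),
          icer_high = unname(stats::quantile(ratios, 0.975)),
          prop_ne = q$NE, prop_nw = q$NW, prop_sw = q$SW, prop_se = q$SE
        ),
        tibble::as_tibble(as.list(probs))
      )
    })
  })
}
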