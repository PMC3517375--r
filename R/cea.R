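#' Per-participant cost/effect inputs for bootstrapping
#'
#' Computes, for one completed (fully observed) dataset, the per-participant
#' cost components and both effect measures, i.e. everything the bootstrap
#' resamples. Costs are re-costed deterministically from the (possibly
#' imputed) resource-use quantities, so the cost identities hold exactly in
#' every completed dataset.
#'
#' @param data Completed analysis tibble (no missing values).
#' @param costs A [unit_cost_table()].
#' @param criteria A [response_criteria()].
#' @param perspective `"societal"` or `"provider"`.
#' @param horizon,method Passed to [qaly()].
#' @return A tibble with `id`, `arm`, the [cost_breakdown()] components,
#'   `responder` (0/1) and `qaly`.
#' @export
cea_inputs <- function(data, costs = unit_cost_table(),
                       criteria = response_criteria(),
                       perspective = c("societal", "provider"),
                       horizon = 0.5, method = "endpoint") {
  perspective <- match.arg(perspective)
  cb <- cost_breakdown(data, costs, perspective = perspective, timepoint = "fu")
  cb$responder <- as.numeric(treatment_response(data, criteria))
  cb$qaly <- qaly(data$utility_base, data$utility_fu, horizon, method)
  cb$utility_fu <- data$utility_fu
  if (anyNA(cb$responder) || anyNA(cb$qaly)) {
    stop("cea_inputs requires completed data (impute first)", call. = FALSE)
  }
  cb
}

# component columns whose within-arm means are tracked per bootstrap draw
cea_components <- function() {
  c("intervention_therapist", "intervention_software", "intervention_total",
    "participant_time", "absenteeism", "presenteeism", "productivity_total",
    "additional_societal", "societal_total", "responder", "qaly",
    "utility_fu")
}

#' Bootstrap the incremental cost-effectiveness distribution
#'
#' From each completed dataset, draws `B` nonparametric bootstrap resamples,
#' stratified by arm (each arm resampled with replacement at its own size,
#' independently, with an independent stream per imputation x replicate), and
#' records the between-arm differences of the within-arm means of every cost
#' component and effect measure. The appended `m x B` draws form the
#' distribution on which medians, planes and acceptability curves are
#' computed.
#'
#' @param x An [impute_trial()] result, a list of completed analysis tibbles,
#'   or a list of precomputed [cea_inputs()] tables.
#' @param costs,criteria,perspective,horizon,method Passed to [cea_inputs()]
#'   when `x` contains raw analysis tables.
#' @param B Bootstrap replicates per imputed dataset (default 1000).
#' @param seed Integer seed.
#' @return An `icer_distribution`: a tibble with one row per draw, columns
#'   `imputation`, `replicate`, `delta_*` for every component (notably
#'   `delta_cost`, `delta_responder`, `delta_qaly`), and arm means
#'   `cost_it`, `cost_is`, `responder_it`, `responder_is`, `qaly_it`,
#'   `qaly_is`. Attributes record `B`, `m`, `n_per_arm` and the seed.
#' @export
bootstrap_cea <- function(x, costs = unit_cost_table(),
                          criteria = response_criteria(),
                          perspective = c("societal", "provider"),
                          B = 1000, seed = 1L, horizon = 0.5,
                          method = "endpoint") {
  perspective <- match.arg(perspective)
  stopifnot(B >= 1)
  datasets <- if (inherits(x, "imputation_set")) x$datasets else x
  if (!is.list(datasets) || !length(datasets)) {
    stop("x must be an imputation set or a non-empty list of datasets",
         call. = FALSE)
  }
  inputs <- lapply(datasets, function(d) {
    if (all(cea_components() %in% names(d))) d
    else cea_inputs(d, costs, criteria, perspective, horizon, method)
  })

  comp <- cea_components()
  set.seed(as.integer(seed))
  stream_seeds <- sample.int(.Machine$integer.max, length(inputs))
  draws <- purrr::imap(inputs, function(inp, k) {
    it <- as.matrix(inp[inp$arm == "IT", comp])
    is_ <- as.matrix(inp[inp$arm == "IS", comp])
    n_it <- nrow(it); n_is <- nrow(is_)
    if (n_it == 0 || n_is == 0) stop("empty arm", call. = FALSE)
    set.seed(stream_seeds[k])
    out <- matrix(NA_real_, B, length(comp) + 6L)
    for (b in seq_len(B)) {
      mit <- colMeans(it[sample.int(n_it, n_it, replace = TRUE), , drop = FALSE])
      mis <- colMeans(is_[sample.int(n_is, n_is, replace = TRUE), , drop = FALSE])
      out[b, ] <- c(mit - mis, mit[c("societal_total", "responder", "qaly")],
                    mis[c("societal_total", "responder", "qaly")])
    }
    colnames(out) <- c(paste0("delta_", comp),
                       c("cost_it", "responder_it", "qaly_it",
                         "cost_is", "responder_is", "qaly_is"))
    dplyr::mutate(tibble::as_tibble(out), imputation = k,
                  replicate = seq_len(B), .before = 1)
  })
  dist <- dplyr::bind_rows(draws)
  dist <- dplyr::rename(dist, delta_cost = "delta_societal_total")
  new_icer_distribution(dist, B = B, m = length(inputs),
                        n_per_arm = c(IT = sum(inputs[[1]]$arm == "IT"),
                                      IS = sum(inputs[[1]]$arm == "IS")),
                        seed = as.integer(seed),
                        perspective = perspective)
}

new_icer_distribution <- function(tbl, B, m, n_per_arm, seed, perspective) {
  structure(tbl, class = c("icer_distribution", class(tbl)),
            B = B, m = m, n_per_arm = n_per_arm, seed = seed,
            perspective = perspective)
}

#' @export
print.icer_distribution <- function(x, ...) {
  cat("<icer_distribution>", nrow(x), "draws (m =", attr(x, "m"),
      "x B =", attr(x, "B"), ") |", attr(x, "perspective"), "perspective\n")
  NextMethod()
}

effect_column <- function(measure = c("responder", "qaly")) {
  paste0("delta_", match.arg(measure, c("responder", "qaly")))
}

#' Point-estimate ICER from mean increments
#'
#' The ratio of the incremental cost to the incremental effect, e.g.
#' 845 / 0.24 = 3521 euro per additional treatment responder and
#' 845 / 0.06 = 14,083 euro per QALY.
#'
#' @param delta_cost_mean Incremental cost (EUR).
#' @param delta_effect_mean Incremental effect (responder proportion or QALY).
#' @return EUR per effect unit.
#' @export
icer_point_estimate <- function(delta_cost_mean, delta_effect_mean) {
  if (any(delta_effect_mean == 0)) {
    cond <- structure(
      class = c("netcea_undefined_icer", "error", "condition"),
      list(message = "ICER undefined: incremental effect is exactly zero",
           call = NULL)
    )
    stop(cond)
  }
  delta_cost_mean / delta_effect_mean
}

#' Median of the bootstrapped ICER distribution
#'
#' Median of the per-draw cost/effect ratios over all appended draws. Draws
#' with exactly zero incremental effect are excluded (their count is attached
#' as the `excluded` attribute and reported via a message). Because raw ratio
#' medians are ill-defined when draws span plane quadrants, the northeast
#' quadrant-restricted variant is available via `quadrant = "ne"`; reports
#' should label which variant they show.
#'
#' @param dist An `icer_distribution`.
#' @param measure `"responder"` or `"qaly"`.
#' @param quadrant `"all"` (default) or `"ne"`.
#' @return Median ICER (EUR per effect unit) with attribute `excluded`.
#' @export
median_icer <- function(dist, measure = c("responder", "qaly"),
                        quadrant = c("all", "ne")) {
  quadrant <- match.arg(quadrant)
  de <- dist[[effect_column(measure)]]
  dc <- dist$delta_cost
  if (!length(de)) stop("empty ICER distribution", call. = FALSE)
  zero <- de == 0
  if (quadrant == "ne") {
    keep <- !zero & de > 0 & dc > 0
  } else {
    keep <- !zero
  }
  if (sum(zero) > 0) {
    message(sum(zero), " draw(s) with zero incremental effect excluded")
  }
  out <- stats::median(dc[keep] / de[keep])
  attr(out, "excluded") <- sum(zero)
  out
}

#' Percentile interval of the bootstrapped ICER
#'
#' 2.5% and 97.5% percentiles of the per-draw ratios on the appended
#' distribution (the only interval type produced).
#'
#' @inheritParams median_icer
#' @param level Coverage (default 0.95).
#' @return Length-2 numeric vector (lower, upper).
#' @export
icer_percentile_interval <- function(dist, measure = c("responder", "qaly"),
                                     level = 0.95) {
  de <- dist[[effect_column(measure)]]
  keep <- de != 0
  r <- dist$delta_cost[keep] / de[keep]
  unname(stats::quantile(r, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Cost-effectiveness plane quadrant proportions
#'
#' Fraction of draws in each plane quadrant: NE (more effect at more cost),
#' NW (less effect at more cost: inferior), SW (less effect at less cost),
#' SE (more effect at less cost: dominant). Boundary ties (a delta exactly
#' zero) are assigned to the positive side; tie counts are attached as the
#' `ties` attribute.
#'
#' @inheritParams median_icer
#' @return A one-row tibble with columns `NE`, `NW`, `SW`, `SE` summing to 1.
#' @export
quadrant_proportions <- function(dist, measure = c("responder", "qaly")) {
  de <- dist[[effect_column(measure)]]
  dc <- dist$delta_cost
  if (!length(de)) stop("empty ICER distribution", call. = FALSE)
  ep <- de >= 0
  cp <- dc >= 0
  out <- tibble::tibble(
    NE = mean(ep & cp),
    NW = mean(!ep & cp),
    SW = mean(!ep & !cp),
    SE = mean(ep & !cp)
  )
  attr(out, "ties") <- sum(de == 0) + sum(dc == 0)
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay (WTP) value, the probability that the
#' intervention is cost effective is the fraction of draws with positive net
#' monetary benefit, `WTP * delta_effect - delta_cost > 0`. The net-benefit
#' formulation handles draws in every plane quadrant; at WTP 0 the curve
#' equals P(delta_cost < 0) and for WTP -> infinity it tends to
#' P(delta_effect > 0).
#'
#' @inheritParams median_icer
#' @param wtp_grid Ascending EUR-per-effect-unit grid (default 0 to 80,000 in
#'   500 EUR steps, covering the usual responder and QALY read-out points).
#' @return A `ceac_curve` tibble with columns `wtp` and `probability`.
#' @export
ceac <- function(dist, wtp_grid = seq(0, 80000, by = 500),
                 measure = c("responder", "qaly")) {
  measure <- match.arg(measure)
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("wtp_grid must be strictly increasing", call. = FALSE)
  }
  de <- dist[[effect_column(measure)]]
  dc <- dist$delta_cost
  prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
  structure(
    tibble::tibble(wtp = wtp_grid, probability = prob),
    class = c("ceac_curve", class(tibble::tibble())),
    measure = measure, n_draws = length(de)
  )
}

#' @export
print.ceac_curve <- function(x, ...) {
  cat("<ceac_curve>", attr(x, "measure"), "effect measure |",
      attr(x, "n_draws"), "draws\n")
  NextMethod()
}

#' Willingness to pay at which a CEAC reaches a probability
#'
#' Smallest grid WTP at which the curve's probability reaches `p`. At
#' `p = 0.5` this is the indifference point above which the intervention is
#' preferred. With `interpolate = TRUE` the crossing is refined by linear
#' interpolation on the segment where the curve first reaches `p` (a finite
#' bootstrap CEAC is a step function, so the grid-point answer is the
#' default).
#'
#' @param curve A [ceac()] result.
#' @param p Target probability.
#' @param interpolate Refine between grid points (default `FALSE`).
#' @return WTP in EUR per effect unit.
#' @export
wtp_at_probability <- function(curve, p = 0.5, interpolate = FALSE) {
  prob <- curve$probability
  wtp <- curve$wtp
  if (prob[1] >= p) return(wtp[1])
  i <- which(prob >= p)
  if (!length(i)) {
    stop(sprintf("the CEAC never reaches probability %.3f on this grid", p),
         call. = FALSE)
  }
  i <- min(i)
  if (!interpolate) return(wtp[i])
  w0 <- wtp[i - 1]; w1 <- wtp[i]
  p0 <- prob[i - 1]; p1 <- prob[i]
  if (p1 == p0) return(w1)
  w0 + (p - p0) / (p1 - p0) * (w1 - w0)
}

#' Probability read-out of a CEAC at given WTP values
#'
#' @param curve A [ceac()] result.
#' @param wtp WTP values (must be on the curve's grid or within its range;
#'   linear interpolation between grid points).
#' @return Probabilities at `wtp`.
#' @export
ceac_at <- function(curve, wtp) {
  stats::approx(curve$wtp, curve$probability, xout = wtp, rule = 2)$y
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarize a bootstrapped ICER distribution
#'
#' One row per effect measure: median incremental cost, median incremental
#' effect, median ICER (all-draw and NE-quadrant variants), the 95%
#' percentile interval, and quadrant proportions.
#'
#' @param x An `icer_distribution`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.icer_distribution <- function(x, ...) {
  purrr::map_dfr(c("responder", "qaly"), function(ms) {
    q <- quadrant_proportions(x, ms)
    ci <- icer_percentile_interval(x, ms)
    med <- suppressMessages(median_icer(x, ms))
    med_ne <- suppressMessages(median_icer(x, ms, quadrant = "ne"))
    tibble::tibble(
      measure = ms,
      delta_cost_median = stats::median(x$delta_cost),
      delta_effect_median = stats::median(x[[effect_column(ms)]]),
      icer_median = as.numeric(med),
      icer_median_ne = as.numeric(med_ne),
      icer_low = ci[1], icer_high = ci[2],
      prop_ne = q$NE, prop_nw = q$NW, prop_sw = q$SW, prop_se = q$SE
    )
  })
}

#' @exportS3Method generics::glance
glance.icer_distribution <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x),
    m = attr(x, "m"),
    B = attr(x, "B"),
    n_it = attr(x, "n_per_arm")[["IT"]],
    n_is = attr(x, "n_per_arm")[["IS"]],
    perspective = attr(x, "perspective"),
    seed = attr(x, "seed")
  )
}

#' @exportS3Method generics::tidy
tidy.ceac_curve <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.ceac_curve <- function(x, ...) {
  ind <- tryCatch(wtp_at_probability(x, 0.5), error = function(e) NA_real_)
  tibble::tibble(
    measure = attr(x, "measure"),
    n_draws = attr(x, "n_draws"),
    wtp_indifference = ind,
    p_at_grid_max = x$probability[nrow(x)]
  )
}

#' Cost-effectiveness plane plot
#'
#' Scatter of the bootstrapped (incremental effect, incremental cost) draws
#' with the plane axes; the comparator sits at the origin.
#'
#' @param object An `icer_distribution`.
#' @param measure `"responder"` or `"qaly"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.icer_distribution <- function(object, measure = c("responder", "qaly"),
                                       ...) {
  measure <- match.arg(measure)
  df <- tibble::tibble(
    delta_effect = object[[effect_column(measure)]],
    delta_cost = object$delta_cost
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_effect,
                                   y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Incremental effect (%s)", measure),
      y = "Incremental cost (EUR)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}

#' Acceptability-curve plot
#'
#' @param object A `ceac_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (EUR per effect unit)",
      y = "P(intervention is cost effective)",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export draw-level and curve tables
#'
#' @param x An `icer_distribution` or `ceac_curve`.
#' @param path CSV path.
#' @export
write_draws <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
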