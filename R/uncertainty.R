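#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of bootstrap draws with strictly positive net monetary
#' benefit `lambda * delta_qaly - delta_cost`. The default grid spans
#' 0-50,000 GBP/QALY in 500 GBP steps, covering the conventional UK
#' 20,000-30,000 GBP/QALY decision range.
#'
#' @param draws Data frame with columns `delta_cost` and `delta_qaly`.
#' @param lambdas Willingness-to-pay grid, GBP per QALY.
#' @return Data frame with `lambda` and `probability`.
#' @export
ceac <- function(draws, lambdas = seq(0, 50000, by = 500)) {
  if (is.null(draws) || nrow(draws) == 0L) stop("no bootstrap draws supplied")
  if (any(!is.finite(draws$delta_cost)) || any(!is.finite(draws$delta_qaly))) {
    stop("bootstrap draws must be finite")
  }
  prob <- vapply(lambdas, function(l) {
    mean(l * draws$delta_qaly - draws$delta_cost > 0)
  }, numeric(1))
  data.frame(lambda = lambdas, probability = prob)
}

#' Intervention cost at which the ICER equals a threshold
#'
#' Solves for the per-patient intervention cost at which the incremental
#' cost-effectiveness ratio equals the willingness-to-pay `lambda`: since
#' lowering the intervention cost by `c0 - c` lowers the incremental cost
#' one-for-one, the threshold cost is `c0 - (delta_cost - lambda *
#' delta_qaly)`.
#'
#' @param delta_cost Base-case incremental cost, GBP (at intervention cost `c0`).
#' @param delta_qaly Base-case incremental QALYs (must be > 0 for a finite
#'   threshold).
#' @param c0 Base-case per-patient intervention cost, GBP.
#' @param lambda Willingness-to-pay, GBP per QALY.
#' @return Threshold cost in GBP per patient.
#' @examples
#' threshold_cost(1745, 0.0465, 981, 30000)  # 631
#' @export
threshold_cost <- function(delta_cost, delta_qaly, c0, lambda) {
  if (!is.finite(delta_qaly) || delta_qaly <= 0) {
    stop("no finite threshold cost: incremental QALYs must be > 0")
  }
  c0 - (delta_cost - lambda * delta_qaly)
}

#' ICERs under alternative intervention delivery costs
#'
#' Re-computes the point-estimate ICER when the intervention is delivered at
#' a different per-patient cost: `(delta_cost - (c0 - c_s)) / delta_qaly`
#' for each scenario cost `c_s`.
#'
#' @inheritParams threshold_cost
#' @param scenario_costs Per-patient intervention costs to evaluate, GBP.
#' @return Data frame with `scenario_cost`, `delta_cost` and `icer`.
#' @export
scenario_icers <- function(delta_cost, delta_qaly, c0,
                           scenario_costs = c(981, 750, 500)) {
  if (!is.finite(delta_qaly) || delta_qaly <= 0) {
    stop("scenario ICERs undefined: incremental QALYs must be > 0")
  }
  dc <- delta_cost - (c0 - scenario_costs)
  data.frame(scenario_cost = scenario_costs, delta_cost = dc,
             icer = dc / delta_qaly)
}

#' One-way sensitivity specification
#'
#' Each parameter is perturbed one at a time from its base value: unit
#' treatment costs and utility decrements by +/-10%, and the discount rate
#' set to 0% and 5%.
#'
#' @param cost_factor Low/high multipliers on unit treatment costs.
#' @param decrement_factor Low/high multipliers on utility decrements.
#' @param discount_rate Low/high discount rates.
#' @return List of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(cost_factor = c(0.9, 1.1),
                             decrement_factor = c(0.9, 1.1),
                             discount_rate = c(0, 0.05)) {
  structure(list(cost_factor = cost_factor,
                 decrement_factor = decrement_factor,
                 discount_rate = discount_rate),
            class = "sensitivity_spec")
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the base-case ICER under each single perturbation of the
#' sensitivity specification, leaving every other parameter at its base
#' value, and orders parameters by the width of the induced ICER range.
#' A perturbation under which incremental QALYs are not positive reports the
#' ICER classification instead of a value.
#'
#' @param evaluate Function `(cost_factor, decrement_factor, discount_rate)`
#'   returning a list with `delta_cost` and `delta_qaly`; it should re-run
#'   the base-case analysis (same seeds) under the perturbed parameters.
#' @param spec A [sensitivity_spec()].
#' @param base Named list of base parameter values.
#' @return Data frame of class `tornado`: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `class_low`, `class_high`, `range`, sorted by
#'   decreasing range.
#' @export
one_way_tornado <- function(evaluate, spec = sensitivity_spec(),
                            base = list(cost_factor = 1, decrement_factor = 1,
                                        discount_rate = 0.035)) {
  eval_at <- function(par, value) {
    args <- base
    args[[par]] <- value
    r <- do.call(evaluate, args)
    ic <- icer(r$delta_cost, r$delta_qaly)
    list(value = ic$value, class = ic$class)
  }
  rows <- lapply(names(spec), function(par) {
    lo <- eval_at(par, spec[[par]][1])
    hi <- eval_at(par, spec[[par]][2])
    rng <- if (lo$class == "finite" && hi$class == "finite")
      abs(hi$value - lo$value) else Inf
    data.frame(parameter = par, low = spec[[par]][1], high = spec[[par]][2],
               icer_low = lo$value, icer_high = hi$value,
               class_low = lo$class, class_high = hi$class, range = rng)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Cost-effectiveness plane data
#'
#' Labels each bootstrap (incremental cost, incremental QALY) pair with its
#' plane quadrant and cost-effectiveness at the supplied thresholds;
#' plot-ready tidy output.
#'
#' @param draws Data frame with `delta_cost`, `delta_qaly` (and optionally a
#'   `scenario` column).
#' @param lambdas Thresholds to flag, GBP per QALY.
#' @return The draws with `quadrant` and one logical column per threshold.
#' @export
ce_plane <- function(draws, lambdas = c(20000, 30000)) {
  if (is.null(draws) || nrow(draws) == 0L) stop("no bootstrap draws supplied")
  draws$quadrant <- ifelse(draws$delta_qaly >= 0,
                           ifelse(draws$delta_cost >= 0, "NE", "SE"),
                           ifelse(draws$delta_cost >= 0, "NW", "SW"))
  for (l in lambdas) {
    draws[[paste0("ce_at_", l)]] <- l * draws$delta_qaly - draws$delta_cost > 0
  }
  draws
}

#' Shift bootstrap draws to an alternative intervention cost
#'
#' Bootstrap incremental costs move one-for-one with the per-patient
#' intervention cost, so scenario clouds for the cost-effectiveness plane
#' and CEAC are obtained by subtracting `c0 - c_s` from each draw.
#'
#' @param draws Data frame with `delta_cost`, `delta_qaly`.
#' @param c0 Base per-patient intervention cost, GBP.
#' @param scenario_cost Alternative per-patient cost, GBP.
#' @return Draws with shifted `delta_cost` and a `scenario` label column.
#' @export
shift_draws <- function(draws, c0, scenario_cost) {
  draws$delta_cost <- draws$delta_cost - (c0 - scenario_cost)
  draws$scenario <- paste0("GBP ", scenario_cost)
  draws
}
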