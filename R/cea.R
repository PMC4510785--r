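#' Classify an incremental cost-effectiveness ratio
#'
#' All sign combinations of (incremental cost, incremental QALYs) are
#' classified: `dominant` when the intervention is cheaper and at least as
#' effective (strictly cheaper with no QALY loss), `dominated` when it costs
#' more and yields fewer QALYs, `infinite` when QALYs are unchanged but cost
#' is higher, `indifferent` at exactly (0, 0), and `finite` otherwise with
#' value `delta_cost / delta_qaly`.
#'
#' @param delta_cost Incremental cost, GBP.
#' @param delta_qaly Incremental QALYs.
#' @param tol Magnitudes below `tol` are treated as exact zeros, so that
#'   numerically-null regression estimates classify as zero effects.
#' @return List with `class` and `value` (`NA` unless finite).
#' @examples
#' icer(1395, 0.0465)    # finite, 30000
#' icer(935, -0.0040)    # dominated
#' icer(285, 0)          # infinite
#' @export
icer <- function(delta_cost, delta_qaly, tol = 1e-9) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  if (abs(delta_cost) < tol) delta_cost <- 0
  if (abs(delta_qaly) < tol) delta_qaly <- 0
  if (delta_qaly == 0) {
    cls <- if (delta_cost > 0) "infinite" else if (delta_cost < 0) "dominant"
           else "indifferent"
    return(list(class = cls, value = NA_real_))
  }
  if (delta_cost > 0 && delta_qaly < 0) return(list(class = "dominated", value = NA_real_))
  if (delta_cost < 0 && delta_qaly > 0) return(list(class = "dominant", value = NA_real_))
  list(class = "finite", value = delta_cost / delta_qaly)
}

#' Covariate-adjusted incremental cost and QALYs
#'
#' Ordinary least squares regression of each per-patient outcome on the
#' treatment-arm indicator plus baseline covariates (centre, age at
#' diagnosis, sex and baseline HbA1c by default). The arm coefficient is the
#' adjusted increment; 95% confidence intervals are normal-theory from the
#' least-squares fit. Covariates constant over the whole sample carry no
#' information and are dropped; a genuinely rank-deficient design is an
#' error naming the collinear columns.
#'
#' @param data Per-patient data frame containing `arm` plus outcome and
#'   covariate columns. `arm` must have levels `routine` (reference) and
#'   `intensive`.
#' @param outcomes Outcome column names (default `cost`, `qaly`).
#' @param covariates Adjustment column names present in `data`.
#' @return List of class `incremental_result`: per outcome `estimate`, `se`,
#'   `ci` (95%), plus `icer` from the point estimates when both `cost` and
#'   `qaly` are present, and `n` per arm.
#' @export
adjusted_increment <- function(data, outcomes = c("cost", "qaly"),
                               covariates = c("centre", "age", "female",
                                              "hba1c_y0")) {
  stopifnot("arm" %in% names(data))
  covariates <- intersect(covariates, names(data))
  if (min(table(data$arm)) < 2) stop("need at least 2 patients per arm")
  keep <- vapply(covariates, function(v) length(unique(data[[v]])) > 1L,
                 logical(1))
  covariates <- covariates[keep]
  data$arm <- factor(data$arm, levels = c("routine", "intensive"))
  rhs <- paste(c("arm", covariates), collapse = " + ")
  res <- lapply(outcomes, function(oc) {
    if (any(is.na(data[[oc]]))) stop("missing values in outcome '", oc, "'")
    if (any(vapply(covariates, function(v) anyNA(data[[v]]), logical(1)))) {
      stop("missing values in covariates; impute first")
    }
    fit <- stats::lm(stats::reformulate(c("arm", covariates), response = oc),
                     data = data)
    co <- stats::coef(fit)
    if (anyNA(co)) {
      stop("rank-deficient design; collinear columns: ",
           paste(names(co)[is.na(co)], collapse = ", "))
    }
    est <- co[["armintensive"]]
    se <- sqrt(diag(stats::vcov(fit)))[["armintensive"]]
    z <- stats::qnorm(0.975)
    list(estimate = est, se = se, ci = c(est - z * se, est + z * se))
  })
  names(res) <- outcomes
  out <- res
  if (all(c("cost", "qaly") %in% outcomes)) {
    out$icer <- icer(res$cost$estimate, res$qaly$estimate)
  }
  out$n <- table(data$arm)
  class(out) <- "incremental_result"
  out
}

#' @export
print.incremental_result <- function(x, ...) {
  for (oc in setdiff(names(x), c("icer", "n"))) {
    cat(sprintf("delta %-5s %10.4f  (95%% CI %.4f, %.4f)\n", oc,
                x[[oc]]$estimate, x[[oc]]$ci[1], x[[oc]]$ci[2]))
  }
  if (!is.null(x$icer)) {
    cat("ICER:", x$icer$class,
        if (x$icer$class == "finite") sprintf("%.0f GBP/QALY", x$icer$value), "\n")
  }
  invisible(x)
}

#' Default phasing of the per-person intervention cost over trial years
#'
#' Delivery costs are charged in year 1, the extra-consultation component is
#' spread evenly over the three intervention years, and the extra-treatment
#' component over five years, consistent with the schedules the cost table
#' records for each category.
#'
#' @param totals A `cost_ledger_totals` (default: packaged cost table).
#' @return Numeric vector of length 5: GBP per person per year.
#' @export
intervention_cost_schedule <- function(totals = ledger_totals(read_cost_items())) {
  pc <- totals$per_person_components
  c(pc[["delivery"]], 0, 0, 0, 0) +
    rep(c(pc[["extra_consultations"]] / 3, 0), c(3, 2)) +
    rep(pc[["extra_treatments"]] / 5, 5)
}

#' Within-trial cumulative cost/QALY table
#'
#' For each horizon, accumulates every patient's discounted cost and QALYs
#' from their observed event history, adds the per-person intervention cost
#' to the intensive arm according to its year schedule, and reports per-arm
#' means with covariate-adjusted increments and the ICER classification.
#' A patient contributes to a horizon only if followed at least that long,
#' so denominators shrink with horizon (censoring-aware rows).
#'
#' @param cohort Cohort with events (see [simulate_trial_events()]).
#' @param tables A `valuation_tables`.
#' @param horizons Integer vector of horizons in years (default 1:5).
#' @param rate Discount rate (default 0.035).
#' @param intervention_schedule GBP per person per year added to the
#'   intensive arm (default [intervention_cost_schedule()]).
#' @param covariates Adjustment covariates, as in [adjusted_increment()].
#' @return Data frame of class `cumulative_table`, one row per horizon.
#' @export
cumulative_table <- function(cohort, tables = read_valuation_tables(),
                             horizons = 1:5, rate = 0.035,
                             intervention_schedule = intervention_cost_schedule(),
                             covariates = c("centre", "age", "female",
                                            "hba1c_y0")) {
  acc <- accumulate_cohort(cohort, max(horizons), rate, tables)
  sched <- c(intervention_schedule,
             rep(0, max(0, max(horizons) - length(intervention_schedule))))
  int_cum <- cumsum(sched * discount_weights(length(sched), rate))
  rows <- lapply(horizons, function(h) {
    inc <- cohort$followup_years >= h
    if (sum(inc & cohort$arm == "routine") < 2 ||
        sum(inc & cohort$arm == "intensive") < 2) {
      warning("horizon ", h, " years exceeds follow-up support; row has n < 2")
      return(data.frame(horizon = h, n_routine = sum(inc & cohort$arm == "routine"),
                        mean_cost_routine = NA, mean_qaly_routine = NA,
                        n_intensive = sum(inc & cohort$arm == "intensive"),
                        mean_cost_intensive = NA, mean_qaly_intensive = NA,
                        delta_cost = NA, delta_cost_lo = NA, delta_cost_hi = NA,
                        delta_qaly = NA, delta_qaly_lo = NA, delta_qaly_hi = NA,
                        icer_class = NA, icer_value = NA))
    }
    d <- cohort[inc, , drop = FALSE]
    d$cost <- acc$cost[inc, h] +
      ifelse(d$arm == "intensive", int_cum[h], 0)
    d$qaly <- acc$qalys[inc, h]
    ai <- adjusted_increment(d, covariates = covariates)
    data.frame(horizon = h,
               n_routine = sum(d$arm == "routine"),
               mean_cost_routine = mean(d$cost[d$arm == "routine"]),
               mean_qaly_routine = mean(d$qaly[d$arm == "routine"]),
               n_intensive = sum(d$arm == "intensive"),
               mean_cost_intensive = mean(d$cost[d$arm == "intensive"]),
               mean_qaly_intensive = mean(d$qaly[d$arm == "intensive"]),
               delta_cost = ai$cost$estimate,
               delta_cost_lo = ai$cost$ci[1], delta_cost_hi = ai$cost$ci[2],
               delta_qaly = ai$qaly$estimate,
               delta_qaly_lo = ai$qaly$ci[1], delta_qaly_hi = ai$qaly$ci[2],
               icer_class = ai$icer$class, icer_value = ai$icer$value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cumulative_table", "data.frame")
  out
}

# internal: cumulative discounted cost/QALY matrices (patient x horizon)
accumulate_cohort <- function(cohort, horizon, rate, tables) {
  n <- nrow(cohort)
  cost <- matrix(0, n, horizon)
  qaly <- matrix(0, n, horizon)
  for (i in seq_len(n)) {
    ev <- if (!is.na(cohort$event_type[i])) {
      data.frame(condition = cohort$event_type[i],
                 year = cohort$event_year[i],
                 fatal = cohort$event_fatal[i])
    } else NULL
    a <- accumulate(ev, horizon, rate, tables)
    cost[i, ] <- cumsum(a$yearly$cost * a$yearly$weight)
    qaly[i, ] <- cumsum(a$yearly$utility * a$yearly$weight)
  }
  list(cost = cost, qalys = qaly)
}
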