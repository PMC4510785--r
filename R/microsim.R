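#' Risk-equation sets for the annual-cycle outcomes microsimulation
#'
#' A risk-equation set parameterizes (a) deterministic annual risk-factor
#' path equations and (b) annual event-probability equations, in the style
#' of published patient-level type 2 diabetes outcomes models (UKPDS-like):
#' the value of a risk factor in year t is a linear function of its baseline
#' value, years since diagnosis and its previous-year value; the probability
#' that an event occurs in year t is a function of age at diagnosis, sex,
#' ethnicity, diabetes duration, previous-year risk-factor values and
#' prevalent-complication flags, through either a logistic link or a Weibull
#' cumulative-hazard link (`p = 1 - exp(-(H(t) - H(t-1)))` with
#' `H(t) = exp(lp) t^shape`).
#'
#' The packaged default set (`risk_equations_synthetic.yaml`) is a synthetic
#' stand-in: the coefficients of the licensed published model are not
#' redistributable, so the defaults are loosely calibrated so that
#' routine-care 30-year cumulative incidences fall in a plausible range for
#' a screen-detected cohort. They are suitable for method development and
#' testing, not for clinical prediction.
#'
#' @param path YAML file with top-level keys `paths` and `events`.
#' @return A list of class `risk_equations`.
#' @export
read_risk_equations <- function(path = system.file("extdata",
                                                   "risk_equations_synthetic.yaml",
                                                   package = "diabcea")) {
  eqs <- yaml::read_yaml(path)
  validate_risk_equations(eqs)
}

#' @rdname read_risk_equations
#' @param eqs A risk-equation list to validate/serialize.
#' @export
validate_risk_equations <- function(eqs) {
  stopifnot(is.list(eqs), !is.null(eqs$paths), !is.null(eqs$events))
  need_f <- c("hba1c", "sbp", "chol", "hdl", "smoker")
  if (!all(need_f %in% names(eqs$paths))) {
    stop("path equations missing for: ",
         paste(setdiff(need_f, names(eqs$paths)), collapse = ", "))
  }
  for (f in names(eqs$paths)) {
    co <- eqs$paths[[f]]
    if (!all(c("intercept", "baseline", "duration", "lag") %in% names(co))) {
      stop("path equation '", f, "' needs intercept/baseline/duration/lag")
    }
  }
  for (e in names(eqs$events)) {
    eq <- eqs$events[[e]]
    if (!eq$link %in% c("logistic", "weibull")) {
      stop("event '", e, "': link must be logistic or weibull")
    }
    if (eq$link == "weibull" && (is.null(eq$shape) || eq$shape <= 0)) {
      stop("event '", e, "': weibull link needs shape > 0")
    }
    if (is.null(eq$coef$intercept)) stop("event '", e, "': missing intercept")
  }
  structure(eqs, class = "risk_equations")
}

#' @rdname read_risk_equations
#' @export
write_risk_equations <- function(eqs, path) {
  yaml::write_yaml(unclass(eqs), path)
  invisible(path)
}

microsim_events <- function(eqs) names(eqs$events)

microsim_morbidity <- function(eqs) {
  setdiff(microsim_events(eqs), c("diabetes_death", "other_death"))
}

#' Deterministic annual risk-factor trajectories
#'
#' Propagates each risk factor year by year from its baseline value via
#' `x_t = intercept + baseline_coef * x_0 + duration_coef * t + lag_coef *
#' x_{t-1}`. Observed measurements at years 0, 1 and 5 (columns `<f>_y0`,
#' `<f>_y1`, `<f>_y5` when present and non-missing) override the simulated
#' values, so the trajectory rejoins the path equation from the observed
#' value. Paths are mean-trajectories: all stochasticity in the simulation
#' enters through event draws.
#'
#' @param patient One-row data frame with baseline (`_y0`) measurement
#'   columns; `_y1`/`_y5` columns are used as overrides when present.
#' @param eqs A `risk_equations` set.
#' @param horizon Years to propagate.
#' @return Matrix `(horizon + 1) x factors`, rows = years 0..horizon.
#' @export
propagate_risk_factors <- function(patient, eqs, horizon) {
  factors <- names(eqs$paths)
  out <- matrix(NA_real_, horizon + 1L, length(factors),
                dimnames = list(0:horizon, factors))
  for (f in factors) {
    base <- patient[[paste0(f, "_y0")]]
    if (is.null(base) || is.na(base)) {
      stop("missing baseline value for risk factor '", f, "'")
    }
    co <- eqs$paths[[f]]
    x <- numeric(horizon + 1L)
    x[1] <- base
    for (t in seq_len(horizon)) {
      x[t + 1L] <- co$intercept + co$baseline * base + co$duration * t +
        co$lag * x[t]
      ov <- patient[[paste0(f, "_y", t)]]
      if (t %in% c(1L, 5L) && !is.null(ov) && !is.na(ov)) x[t + 1L] <- ov
    }
    out[, f] <- x
  }
  out
}

#' Microsimulation run configuration
#'
#' @param horizon Simulation horizon in years.
#' @param inner_loops Monte-Carlo passes per patient; the per-patient
#'   expectation is the inner-loop mean (default 1000).
#' @param bootstraps Patient-level bootstrap replicates for uncertainty
#'   analysis (default 100).
#' @param discount_rate Annual discount rate (default 0.035).
#' @param seed Integer seed.
#' @param horizons Reporting horizons (subset of 1..horizon).
#' @param intervention_annual_cost Continuing extra-prescription cost, GBP
#'   per alive intensive-arm patient-year (default 262.5).
#' @param intervention_upfront GBP per intensive-arm person per year for the
#'   one-off delivery and extra-consultation components (default: delivery
#'   in year 1, consultations spread over years 1-3, from the packaged cost
#'   table).
#' @param cost_factor,decrement_factor One-way sensitivity multipliers on
#'   unit treatment costs and utility decrements (default 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(horizon = 30, inner_loops = 1000, bootstraps = 100,
                       discount_rate = 0.035, seed = 1L,
                       horizons = c(10, 20, 30),
                       intervention_annual_cost = 262.5,
                       intervention_upfront = NULL,
                       cost_factor = 1, decrement_factor = 1) {
  stopifnot(horizon >= 1, inner_loops >= 1, bootstraps >= 0,
            discount_rate >= 0)
  horizons <- sort(unique(pmin(horizons, horizon)))
  structure(list(horizon = horizon, inner_loops = inner_loops,
                 bootstraps = bootstraps, discount_rate = discount_rate,
                 seed = seed, horizons = horizons,
                 intervention_annual_cost = intervention_annual_cost,
                 intervention_upfront = intervention_upfront,
                 cost_factor = cost_factor,
                 decrement_factor = decrement_factor),
            class = "sim_config")
}

# annual event probability for a vector of linear predictors
event_prob <- function(lp, eq, t, name) {
  p <- if (eq$link == "logistic") {
    stats::plogis(lp)
  } else {
    1 - exp(-exp(lp) * (t^eq$shape - (t - 1)^eq$shape))
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("event equation '", name, "' produced a probability outside [0, 1]")
  }
  p
}

# linear-predictor pieces that do not depend on prevalent flags
base_lp <- function(eq, patient, rf, t) {
  co <- eq$coef
  g <- function(nm) if (is.null(co[[nm]])) 0 else co[[nm]]
  co$intercept +
    g("age_diag") * patient$age +
    g("female") * as.numeric(patient$female) +
    g("afro") * as.numeric(patient$ethnicity == "afro_caribbean") +
    g("asian") * as.numeric(patient$ethnicity == "asian_indian") +
    g("duration") * t +
    g("hba1c") * rf[t, "hba1c"] +
    g("sbp") * rf[t, "sbp"] +
    g("chol") * rf[t, "chol"] +
    g("hdl") * rf[t, "hdl"] +
    g("smoker") * rf[t, "smoker"]
}

hist_coefs <- function(eq, morbidity) {
  vapply(morbidity, function(e2) {
    v <- eq$coef[[paste0("hist_", e2)]]
    if (is.null(v)) 0 else v
  }, numeric(1))
}

#' Simulate one patient's long-term outcomes
#'
#' Annual-cycle patient-level simulation: each year, each non-prevalent
#' complication is sampled independently from its annual probability (risk
#' factors follow their deterministic paths, lagged one year); the two death
#' causes are drawn last, so a death year still records same-year morbidity.
#' Costs and QALYs accumulate through the additive valuation engine
#' (complication-free years cost the base diabetes cost and score
#' 1 - 0.220 = 0.780), discounted after year 1; death by diabetes is charged
#' the cardiovascular-death cost; intensive-arm patients additionally accrue
#' the continuing prescription cost each alive year. The per-patient
#' expectation is the mean over inner loops. All complication flags start
#' at zero (newly diagnosed cohort).
#'
#' @param patient One-row cohort data frame.
#' @param eqs A `risk_equations` set.
#' @param config A [sim_config()].
#' @param tables A `valuation_tables`.
#' @return List with per-horizon means `cost` and `qaly` (named by horizon),
#'   `cuminc` (matrix year x event of cumulative incidence across loops),
#'   and per-loop draws at the full horizon (`cost_draws`, `qaly_draws`).
#' @export
simulate_patient <- function(patient, eqs, config = sim_config(),
                             tables = read_valuation_tables()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  H <- config$horizon
  L <- config$inner_loops
  morb <- microsim_morbidity(eqs)
  deaths <- intersect(c("diabetes_death", "other_death"), microsim_events(eqs))
  rf <- propagate_risk_factors(patient, eqs, H)
  cf <- config$cost_factor
  uf <- config$decrement_factor
  base_cost <- tables["t2dm", "cost_event_nonfatal"] * cf
  ev_cost <- tables[morb, "cost_event_nonfatal"] * cf
  sub_cost <- tables[morb, "cost_subsequent"] * cf
  dec0 <- tables["t2dm", "utility_decrement"] * uf
  decs <- tables[morb, "utility_decrement"] * uf
  dd_cost <- tables["cvd_death", "cost_event_fatal"] * cf
  int_cost <- if (identical(patient$arm, "intensive"))
    config$intervention_annual_cost else 0
  upfront <- config$intervention_upfront
  w <- discount_weights(H, config$discount_rate)

  nm <- length(morb)
  flags <- matrix(FALSE, L, nm, dimnames = list(NULL, morb))
  alive <- rep(TRUE, L)
  cost_cum <- numeric(L)
  qaly_cum <- numeric(L)
  ever <- matrix(0, H, nm + length(deaths),
                 dimnames = list(NULL, c(morb, deaths)))
  snap_cost <- matrix(NA_real_, L, length(config$horizons))
  snap_qaly <- matrix(NA_real_, L, length(config$horizons))
  lp0 <- matrix(NA_real_, H, nm + length(deaths),
                dimnames = list(NULL, c(morb, deaths)))
  for (e in c(morb, deaths)) {
    for (t in seq_len(H)) lp0[t, e] <- base_lp(eqs$events[[e]], patient, rf, t)
  }
  hco <- lapply(c(morb, deaths), function(e) hist_coefs(eqs$events[[e]], morb))
  names(hco) <- c(morb, deaths)

  for (t in seq_len(H)) {
    prev <- flags
    incid <- matrix(FALSE, L, nm, dimnames = list(NULL, morb))
    if (any(alive)) {
      for (e in morb) {
        at_risk <- alive & !flags[, e]
        if (!any(at_risk)) next
        lp <- lp0[t, e] + as.vector(flags %*% hco[[e]])
        p <- event_prob(lp, eqs$events[[e]], t, e)
        incid[, e] <- at_risk & stats::runif(L) < p
      }
      flags <- flags | incid
      died_dd <- rep(FALSE, L)
      died_od <- rep(FALSE, L)
      if ("diabetes_death" %in% deaths) {
        lp <- lp0[t, "diabetes_death"] +
          as.vector(flags %*% hco[["diabetes_death"]])
        p <- event_prob(lp, eqs$events[["diabetes_death"]], t, "diabetes_death")
        died_dd <- alive & stats::runif(L) < p
      }
      if ("other_death" %in% deaths) {
        lp <- lp0[t, "other_death"] + as.vector(flags %*% hco[["other_death"]])
        p <- event_prob(lp, eqs$events[["other_death"]], t, "other_death")
        died_od <- alive & !died_dd & stats::runif(L) < p
      }
      year_cost <- alive * (base_cost + int_cost +
                              as.vector(prev %*% sub_cost)) +
        as.vector(incid %*% ev_cost) + died_dd * dd_cost
      if (!is.null(upfront) && t <= length(upfront) &&
          identical(patient$arm, "intensive")) {
        year_cost <- year_cost + alive * upfront[t]
      }
      survives <- alive & !died_dd & !died_od
      year_utility <- survives * pmax(0, 1 - dec0 - as.vector(flags %*% decs))
      cost_cum <- cost_cum + w[t] * year_cost
      qaly_cum <- qaly_cum + w[t] * year_utility
      alive <- survives
      if (t == 1L) {
        dd_ever <- died_dd; od_ever <- died_od
      } else {
        dd_ever <- dd_ever | died_dd; od_ever <- od_ever | died_od
      }
    } else if (t == 1L) {
      dd_ever <- rep(FALSE, L); od_ever <- rep(FALSE, L)
    }
    ever[t, morb] <- colMeans(flags)
    if ("diabetes_death" %in% deaths) ever[t, "diabetes_death"] <- mean(dd_ever)
    if ("other_death" %in% deaths) ever[t, "other_death"] <- mean(od_ever)
    hs <- match(t, config$horizons)
    if (!is.na(hs)) {
      snap_cost[, hs] <- cost_cum
      snap_qaly[, hs] <- qaly_cum
    }
  }
  list(cost = stats::setNames(colMeans(snap_cost), config$horizons),
       qaly = stats::setNames(colMeans(snap_qaly), config$horizons),
       cuminc = ever,
       cost_draws = cost_cum, qaly_draws = qaly_cum)
}

#' Extrapolate imputed cohorts with the outcomes microsimulation
#'
#' Runs [simulate_patient()] for every patient of every completed
#' (imputed) cohort, then, per reporting horizon: covariate-adjusted
#' incremental cost and QALYs (OLS on the per-patient inner-loop means,
#' adjusting for centre, age at diagnosis, sex and baseline HbA1c), per-arm
#' cumulative event incidences with the same linear adjustment applied to
#' the per-patient incidence fractions, pooling across imputations by
#' Rubin's rules, and patient-level bootstrap draws of the incremental pair
#' feeding the decision-uncertainty layer (bootstrap replicates cycle
#' through the imputations).
#'
#' @param cohorts A cohort data frame or list of `m` completed cohorts.
#' @param eqs A `risk_equations` set.
#' @param config A [sim_config()].
#' @param tables A `valuation_tables`.
#' @param covariates Adjustment covariates.
#' @return List of class `extrapolation` with `increments` (per horizon:
#'   pooled `cost`, `qaly` with CIs, and `icer`), `incidence` (data frame:
#'   event, horizon, per-arm means, adjusted difference, SE), `draws` (data
#'   frame of bootstrap `delta_cost`/`delta_qaly` pairs per horizon) and
#'   `per_patient` (inner-loop means, imputation-stacked).
#' @export
cohort_extrapolate <- function(cohorts, eqs, config = sim_config(),
                               tables = read_valuation_tables(),
                               covariates = c("centre", "age", "female",
                                              "hba1c_y0")) {
  if (is.data.frame(cohorts)) cohorts <- list(cohorts)
  m <- length(cohorts)
  horizons <- config$horizons
  events <- microsim_events(eqs)
  per_imp <- vector("list", m)
  for (i in seq_len(m)) {
    co <- cohorts[[i]]
    n <- nrow(co)
    res <- vector("list", n)
    for (j in seq_len(n)) {
      pcfg <- config
      pcfg$seed <- (config$seed + 7919L * i + j) %% .Machine$integer.max
      res[[j]] <- simulate_patient(co[j, , drop = FALSE], eqs, pcfg, tables)
    }
    pp <- co[, intersect(c("id", "arm", "centre", "age", "female", "hba1c_y0"),
                         names(co)), drop = FALSE]
    for (h in horizons) {
      pp[[paste0("cost_", h)]] <- vapply(res, function(r) r$cost[[as.character(h)]], numeric(1))
      pp[[paste0("qaly_", h)]] <- vapply(res, function(r) r$qaly[[as.character(h)]], numeric(1))
      for (e in events) {
        pp[[paste0("inc_", e, "_", h)]] <-
          vapply(res, function(r) r$cuminc[h, e], numeric(1))
      }
    }
    pp$imputation <- i
    per_imp[[i]] <- pp
  }

  adjust_one <- function(pp, ycol) {
    d <- pp
    d$y <- pp[[ycol]]
    ai <- adjusted_increment(d, outcomes = "y", covariates = covariates)
    c(est = ai$y$estimate, var = ai$y$se^2)
  }
  increments <- list()
  incidence <- NULL
  for (h in horizons) {
    pool <- function(col) {
      ev <- t(vapply(per_imp, adjust_one, numeric(2), ycol = col))
      if (m >= 2) rubins_pool(ev[, "est"], ev[, "var"])
      else {
        se <- sqrt(ev[1, "var"])
        list(estimate = ev[1, "est"], variance = ev[1, "var"],
             ci = ev[1, "est"] + c(-1, 1) * stats::qnorm(0.975) * se)
      }
    }
    pc <- pool(paste0("cost_", h))
    pq <- pool(paste0("qaly_", h))
    increments[[as.character(h)]] <-
      list(cost = pc, qaly = pq, icer = icer(pc$estimate, pq$estimate))
    for (e in events) {
      col <- paste0("inc_", e, "_", h)
      pe <- pool(col)
      stacked <- do.call(rbind, per_imp)
      incidence <- rbind(incidence, data.frame(
        event = e, horizon = h,
        routine = mean(stacked[[col]][stacked$arm == "routine"]),
        intensive = mean(stacked[[col]][stacked$arm == "intensive"]),
        adj_difference = pe$estimate, se = sqrt(pe$variance)))
    }
  }

  draws <- NULL
  if (config$bootstraps > 0) {
    set.seed(config$seed)
    for (b in seq_len(config$bootstraps)) {
      pp <- per_imp[[(b - 1L) %% m + 1L]]
      idx <- sample.int(nrow(pp), replace = TRUE)
      bs <- pp[idx, , drop = FALSE]
      if (length(unique(bs$arm)) < 2L || min(table(bs$arm)) < 2L) next
      for (h in horizons) {
        dc <- adjust_one(bs, paste0("cost_", h))[["est"]]
        dq <- adjust_one(bs, paste0("qaly_", h))[["est"]]
        draws <- rbind(draws, data.frame(replicate = b, horizon = h,
                                         delta_cost = dc, delta_qaly = dq))
      }
    }
  }
  structure(list(horizons = horizons, increments = increments,
                 incidence = incidence, draws = draws,
                 per_patient = do.call(rbind, per_imp)),
            class = "extrapolation")
}

#' @export
print.extrapolation <- function(x, ...) {
  for (h in names(x$increments)) {
    inc <- x$increments[[h]]
    cat(sprintf("%s years: delta cost %.0f GBP (%.0f, %.0f); delta QALY %.4f (%.4f, %.4f); ICER %s\n",
                h, inc$cost$estimate, inc$cost$ci[1], inc$cost$ci[2],
                inc$qaly$estimate, inc$qaly$ci[1], inc$qaly$ci[2],
                if (inc$icer$class == "finite")
                  sprintf("%.0f GBP/QALY", inc$icer$value) else inc$icer$class))
  }
  invisible(x)
}
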