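#' Read per-condition unit costs and utility decrements
#'
#' Loads the valuation table used to convert a patient's annual health state
#' into that year's cost (GBP, 2009/10) and utility weight. One row per
#' condition with the cost in the year of the event (fatal and non-fatal),
#' the annual cost in subsequent years, and the additive utility decrement
#' (stored as a positive magnitude; uncomplicated type 2 diabetes carries a
#' decrement of 0.220 so an event-free year scores 0.780).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A data frame of class `valuation_tables`, one row per condition,
#'   with row names `t2dm`, `ihd`, `mi`, `heart_failure`, `stroke`,
#'   `revascularization`, `amputation`, `blindness`, `renal_failure`,
#'   `cvd_death`.
#' @export
read_valuation_tables <- function(path = system.file("extdata", "valuation_tables.csv",
                                                     package = "diabcea")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("condition", "cost_event_fatal", "cost_event_nonfatal",
              "cost_subsequent", "utility_decrement")
  if (!all(needed %in% names(tab))) {
    stop("valuation table lacks columns: ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  }
  rownames(tab) <- tab$condition
  costs <- as.matrix(tab[, c("cost_event_fatal", "cost_event_nonfatal",
                             "cost_subsequent")])
  if (any(costs < 0, na.rm = TRUE)) stop("valuation costs must be >= 0")
  dec <- tab$utility_decrement
  if (any(dec < 0 | dec > 1, na.rm = TRUE)) {
    stop("utility decrements must lie in [0, 1]")
  }
  class(tab) <- c("valuation_tables", "data.frame")
  tab
}

#' Scale a valuation table's costs or decrements
#'
#' One-way sensitivity helper: multiplies all unit treatment costs and/or
#' all utility decrements by a constant factor.
#'
#' @param tables A `valuation_tables` object.
#' @param cost_factor Multiplier on every cost column.
#' @param decrement_factor Multiplier on every utility decrement.
#' @return The scaled `valuation_tables`.
#' @export
scale_valuation <- function(tables, cost_factor = 1, decrement_factor = 1) {
  stopifnot(inherits(tables, "valuation_tables"))
  for (col in c("cost_event_fatal", "cost_event_nonfatal", "cost_subsequent")) {
    tables[[col]] <- tables[[col]] * cost_factor
  }
  tables$utility_decrement <- tables$utility_decrement * decrement_factor
  tables
}

check_conditions <- function(conditions, tables) {
  unknown <- setdiff(conditions, rownames(tables))
  if (length(unknown) > 0L) {
    stop("unknown condition(s): ", paste(unknown, collapse = ", "))
  }
}

#' One patient-year health state
#'
#' @param year Year index (t >= 1).
#' @param prevalent Character vector of conditions present before this year.
#' @param incident Character vector of events occurring this year.
#' @param incident_fatal Logical vector parallel to `incident`.
#' @param alive_at_start Was the patient alive at the start of the year?
#' @param died_this_year Did the patient die during the year?
#' @return A list of class `patient_year_state`.
#' @export
year_state <- function(year = 1L, prevalent = character(),
                       incident = character(),
                       incident_fatal = logical(length(incident)),
                       alive_at_start = TRUE,
                       died_this_year = any(incident_fatal)) {
  stopifnot(year >= 1, length(incident_fatal) == length(incident))
  if (!alive_at_start && length(incident) > 0L) {
    stop("dead patients cannot have incident events")
  }
  if (sum(incident_fatal) > 1L) stop("at most one fatal event per patient")
  structure(list(year = as.integer(year), prevalent = unique(prevalent),
                 incident = incident, incident_fatal = incident_fatal,
                 alive_at_start = alive_at_start,
                 died_this_year = died_this_year),
            class = "patient_year_state")
}

#' Annual cost of a patient-year state
#'
#' Additive costing: the base annual cost of uncomplicated type 2 diabetes
#' (charged while alive at the start of the year) plus the event-year cost of
#' each incident event (fatal or non-fatal column per its flag) plus the
#' subsequent-year cost of each prevalent complication. Years fully after
#' death cost zero. A fatal event whose condition carries no specific fatal
#' cost is charged the standalone cardiovascular-death cost.
#'
#' @param state A `patient_year_state`.
#' @param tables A `valuation_tables`.
#' @return Cost in GBP.
#' @export
annual_cost <- function(state, tables) {
  stopifnot(inherits(state, "patient_year_state"),
            inherits(tables, "valuation_tables"))
  if (!state$alive_at_start) return(0)
  check_conditions(c(state$prevalent, state$incident), tables)
  cost <- tables["t2dm", "cost_event_nonfatal"]
  if (length(state$incident) > 0L) {
    for (i in seq_along(state$incident)) {
      cond <- state$incident[i]
      if (state$incident_fatal[i]) {
        fatal_cost <- tables[cond, "cost_event_fatal"]
        if (is.na(fatal_cost)) fatal_cost <- tables["cvd_death", "cost_event_fatal"]
        cost <- cost + fatal_cost
      } else {
        cost <- cost + tables[cond, "cost_event_nonfatal"]
      }
    }
  }
  prev <- setdiff(state$prevalent, c("t2dm", "cvd_death"))
  if (length(prev) > 0L) {
    cost <- cost + sum(tables[prev, "cost_subsequent"], na.rm = TRUE)
  }
  cost
}

#' Annual utility weight of a patient-year state
#'
#' Additive decrements from full health: `1 - 0.220 - sum of condition
#' decrements` over the union of prevalent and incident conditions, floored
#' at 0. The same decrement applies in the event year and all subsequent
#' years. The year of death (and all later years) scores 0.
#'
#' @inheritParams annual_cost
#' @return Utility weight in `[0, 1]`.
#' @export
annual_utility <- function(state, tables) {
  stopifnot(inherits(state, "patient_year_state"),
            inherits(tables, "valuation_tables"))
  if (!state$alive_at_start || state$died_this_year) return(0)
  check_conditions(c(state$prevalent, state$incident), tables)
  conds <- setdiff(unique(c(state$prevalent, state$incident)),
                   c("t2dm", "cvd_death"))
  dec <- tables["t2dm", "utility_decrement"]
  if (length(conds) > 0L) {
    dec <- dec + sum(tables[conds, "utility_decrement"], na.rm = TRUE)
  }
  max(0, 1 - dec)
}

# internal: build the sequence of year states from an event history
# events: data.frame(condition, year, fatal)
event_year_states <- function(events, horizon) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(condition = character(), year = integer(),
                         fatal = logical())
  }
  if (sum(events$fatal) > 1L) stop("at most one fatal event per patient")
  if (nrow(events) > 0L && any(events$year < 0)) stop("event year must be >= 0")
  death_year <- if (any(events$fatal)) min(events$year[events$fatal]) else Inf
  lapply(seq_len(horizon), function(t) {
    inc <- events[events$year == t & events$year <= death_year, , drop = FALSE]
    prev <- unique(events$condition[events$year < t & !events$fatal])
    year_state(year = t, prevalent = prev, incident = inc$condition,
               incident_fatal = inc$fatal,
               alive_at_start = t <= death_year,
               died_this_year = t == death_year)
  })
}

#' Discounted cost and QALYs over an event history
#'
#' Values a patient's event history year by year over a horizon, discounting
#' both costs and QALYs after the first year at `rate`. Events become
#' prevalent from the following year onward; a fatal event stops all accrual
#' after its year (cost charged, death-year utility 0).
#'
#' @param events Data frame with columns `condition`, `year` (integer year
#'   index, 1-based) and `fatal` (logical). `NULL` or zero rows means an
#'   event-free history.
#' @param horizon Number of years (>= 1).
#' @param rate Annual discount rate (default 0.035).
#' @param tables A `valuation_tables`.
#' @return List with `cost` (GBP) and `qalys`.
#' @export
accumulate <- function(events, horizon, rate = 0.035,
                       tables = read_valuation_tables()) {
  if (!is.numeric(horizon) || horizon < 1) stop("horizon must be >= 1")
  horizon <- as.integer(horizon)
  states <- event_year_states(events, horizon)
  w <- discount_weights(horizon, rate)
  costs <- vapply(states, annual_cost, numeric(1), tables = tables)
  utils_ <- vapply(states, annual_utility, numeric(1), tables = tables)
  list(cost = sum(costs * w), qalys = sum(utils_ * w),
       yearly = data.frame(year = seq_len(horizon), cost = costs,
                           utility = utils_, weight = w))
}
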