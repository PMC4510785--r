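# Shared fixtures and independent oracles, built in code at test time.

the_tables <- read_valuation_tables()

# annuity factor: sum_{t=1..n} (1+r)^-(t-1), computed independently of the
# package's discounting code
annuity <- function(n, r) sum((1 + r)^-(0:(n - 1)))

# hand-built event-free cohort: deterministic covariates with pairwise
# coprime cycle lengths so the default adjustment design has full rank
flat_cohort <- function(n_per_arm = 20, followup = 5) {
  n <- 2 * n_per_arm
  id <- seq_len(n)
  data.frame(
    id = id,
    arm = rep(c("routine", "intensive"), each = n_per_arm),
    centre = rep(c("Cambridge", "Cambridge", "Leicester"), length.out = n),
    age = 50 + (id %% 7) * 2,
    female = id %% 2 == 0,
    ethnicity = "caucasian",
    hba1c_y0 = 6 + (id %% 5) * 0.5,
    followup_years = followup,
    event_type = NA_character_, event_time = NA_real_,
    event_year = NA_integer_, event_fatal = FALSE, alive = TRUE,
    stringsAsFactors = FALSE)
}

# one-row patient for the microsimulation
toy_patient <- function(arm = "routine") {
  data.frame(arm = arm, age = 60, female = FALSE, ethnicity = "caucasian",
             hba1c_y0 = 7.3, sbp_y0 = 143, chol_y0 = 5.5, hdl_y0 = 1.2,
             smoker_y0 = 0, stringsAsFactors = FALSE)
}

# identity risk-factor paths (constant at baseline), no covariate effects
toy_paths <- function() {
  lapply(stats::setNames(nm = c("hba1c", "sbp", "chol", "hdl", "smoker")),
         function(f) list(intercept = 0, baseline = 0, duration = 0, lag = 1))
}

# two-event toy equation set: one morbidity (mi) and one death cause, each
# with a constant annual probability
toy_eqs <- function(p_mi, p_death) {
  validate_risk_equations(list(
    paths = toy_paths(),
    events = list(
      mi = list(link = "logistic", coef = list(intercept = stats::qlogis(p_mi))),
      diabetes_death = list(link = "logistic",
                            coef = list(intercept = stats::qlogis(p_death))))))
}

# exact expectation for the two-event toy model by dynamic programming over
# the state distribution (alive x mi-flag), mirroring the valuation rules:
# morbidity drawn first, death last; death year charges the CVD-death cost
# and scores zero utility. Independent of the simulation code.
enum_expected <- function(p_mi, p_death, horizon, rate, tables) {
  base <- tables["t2dm", "cost_event_nonfatal"]
  ev <- tables["mi", "cost_event_nonfatal"]
  sub <- tables["mi", "cost_subsequent"]
  dd <- tables["cvd_death", "cost_event_fatal"]
  u0 <- 1 - tables["t2dm", "utility_decrement"]
  u1 <- u0 - tables["mi", "utility_decrement"]
  # state probabilities: alive without mi, alive with mi, dead
  pr <- c(a0 = 1, a1 = 0, dead = 0)
  cost <- 0; qaly <- 0
  for (t in seq_len(horizon)) {
    w <- (1 + rate)^-(t - 1)
    # from a0: mi this year w.p. p_mi; death w.p. p_death (independent)
    inc_mi <- pr["a0"] * p_mi
    year_cost <- (pr["a0"] + pr["a1"]) * base + inc_mi * ev +
      pr["a1"] * sub + (pr["a0"] + pr["a1"]) * p_death * dd
    surv_a0 <- pr["a0"] * (1 - p_mi) * (1 - p_death)
    surv_a1 <- (pr["a1"] + inc_mi) * (1 - p_death)
    year_qaly <- unname(surv_a0 * u0 + surv_a1 * u1)
    cost <- cost + w * unname(year_cost)
    qaly <- qaly + w * year_qaly
    pr <- c(a0 = unname(surv_a0), a1 = unname(surv_a1),
            dead = unname(1 - surv_a0 - surv_a1))
  }
  list(cost = cost, qalys = qaly)
}

# ordinary least squares by the normal equations, independent of lm
ols_oracle <- function(y, X) solve(crossprod(X), crossprod(X, y))
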