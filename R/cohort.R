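#' Configuration for the synthetic trial-cohort generator
#'
#' Defines the statistical structure of a synthetic two-arm (routine care vs
#' intensive treatment) cohort of people with screen-detected type 2
#' diabetes: per-arm baseline distributions, centre allocation, constant
#' first-cardiovascular-event hazards, follow-up distribution and MCAR
#' missingness. Defaults reproduce the published baseline table of the UK
#' trial the analysis emulates: 511/513 participants, mean age 60.1 (sd 7.5)
#' vs 61.1 (7.2) years, routine-arm first-event hazard 15.9 per 1000
#' person-years with an intensive-arm hazard ratio of 0.83, and follow-up
#' normal(5.0, 1.1) truncated to [1, 6] years.
#'
#' @param n_routine,n_intensive Arm sizes.
#' @param routine,intensive Per-arm baseline distribution lists; see the
#'   default for the required fields (`age`, `bmi`, `chol`, `hdl`, `sbp`,
#'   `hba1c` as `c(mean, sd)`; `female`, `caucasian`, `smoker` as
#'   proportions).
#' @param centre_prop_cambridge Proportion of patients allocated to the
#'   Cambridge centre (remainder Leicester).
#' @param cvd_hazard_routine Constant first-CVD-event hazard in the routine
#'   arm, events per person-year.
#' @param hazard_ratio_intensive Intensive:routine hazard ratio.
#' @param followup `c(mean, sd)` of follow-up in years.
#' @param followup_bounds Truncation bounds for follow-up, years. The
#'   default `c(1, 9)` is symmetric about the mean, so truncation leaves
#'   the configured mean and sd essentially unchanged.
#' @param missing_rate MCAR missingness probability per imputable cell.
#' @param treatment_effect Additive shift of intensive-arm risk-factor
#'   measurements at years 1 and 5 (negative = improvement), named
#'   `sbp` (mmHg), `hba1c` (%), `chol` (mmol/l).
#' @param secular_change Additive change common to both arms by year 5
#'   (half applied by year 1), same names as `treatment_effect`.
#' @param measurement_noise Re-measurement noise sd at years 1 and 5, named
#'   `sbp`, `hba1c`, `chol`, `hdl`.
#' @param quit_prob Annual-ish probabilities that a baseline smoker has quit
#'   by year 1 and by year 5, `c(y1, y5)`.
#' @param event_mix Named probabilities over first-event types.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_routine = 511, n_intensive = 513,
                          routine = list(age = c(60.1, 7.5), female = 0.407,
                                         caucasian = 0.867, smoker = 0.180,
                                         bmi = c(33.0, 5.9), chol = c(5.5, 1.2),
                                         hdl = c(1.2, 0.3), sbp = c(143.1, 19.4),
                                         hba1c = c(7.3, 1.7)),
                          intensive = list(age = c(61.1, 7.2), female = 0.366,
                                           caucasian = 0.918, smoker = 0.177,
                                           bmi = c(33.1, 5.6), chol = c(5.3, 1.1),
                                           hdl = c(1.2, 0.4), sbp = c(142.0, 20.1),
                                           hba1c = c(7.3, 1.7)),
                          centre_prop_cambridge = 867 / 1026,
                          cvd_hazard_routine = 0.0159,
                          hazard_ratio_intensive = 0.83,
                          followup = c(5.0, 1.1),
                          followup_bounds = c(1, 9),
                          missing_rate = 0,
                          treatment_effect = c(sbp = -1.5, hba1c = -0.06,
                                               chol = -0.2),
                          secular_change = c(sbp = -4.5, hba1c = 0, chol = -0.1),
                          measurement_noise = c(sbp = 8, hba1c = 0.5,
                                                chol = 0.4, hdl = 0.1),
                          quit_prob = c(0.03, 0.10),
                          event_mix = c(mi = 0.30, stroke = 0.25,
                                        revascularization = 0.25,
                                        amputation = 0.05, cvd_death = 0.15)) {
  cfg <- list(n_routine = n_routine, n_intensive = n_intensive,
              routine = routine, intensive = intensive,
              centre_prop_cambridge = centre_prop_cambridge,
              cvd_hazard_routine = cvd_hazard_routine,
              hazard_ratio_intensive = hazard_ratio_intensive,
              followup = followup, followup_bounds = followup_bounds,
              missing_rate = missing_rate,
              treatment_effect = treatment_effect,
              secular_change = secular_change,
              measurement_noise = measurement_noise,
              quit_prob = quit_prob, event_mix = event_mix)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  err <- function(...) stop("cohort configuration error: ", ..., call. = FALSE)
  if (cfg$n_routine < 1 || cfg$n_intensive < 1) err("arm sizes must be >= 1")
  props <- c(cfg$centre_prop_cambridge, cfg$missing_rate,
             cfg$routine$female, cfg$routine$caucasian, cfg$routine$smoker,
             cfg$intensive$female, cfg$intensive$caucasian,
             cfg$intensive$smoker, cfg$quit_prob, cfg$event_mix)
  if (any(props < 0 | props > 1)) err("all proportions must lie in [0, 1]")
  for (arm in c("routine", "intensive")) {
    for (v in c("age", "bmi", "chol", "hdl", "sbp", "hba1c")) {
      par <- cfg[[arm]][[v]]
      if (length(par) != 2L || is.na(par[2]) || par[2] < 0) {
        err(arm, " ", v, " must be c(mean, sd) with sd >= 0")
      }
    }
  }
  if (cfg$cvd_hazard_routine <= 0 || cfg$hazard_ratio_intensive <= 0) {
    err("hazards must be > 0")
  }
  if (cfg$followup[2] < 0) err("follow-up sd must be >= 0")
  if (abs(sum(cfg$event_mix) - 1) > 1e-8) err("event_mix must sum to 1")
  invisible(cfg)
}

# truncated-normal draws by inverse CDF; degenerate at the mean when sd = 0
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic two-arm trial cohort
#'
#' Draws per-arm baseline covariates from the configured distributions,
#' assigns centre, sex, ethnicity (non-Caucasian remainder split equally
#' between Afro-Caribbean and Asian-Indian), fixed-per-sex height with weight
#' derived from BMI, truncated-normal follow-up, and risk-factor
#' re-measurements at years 1 and 5 that drift from baseline by a common
#' secular change plus an intensive-arm treatment effect. HDL is constrained
#' below total cholesterol at every time point. Deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A data frame, one row per patient, with wide year-indexed
#'   measurement columns (`sbp_y0`, `sbp_y1`, `sbp_y5`, ...).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  set.seed(seed)
  arms <- list(routine = config$n_routine, intensive = config$n_intensive)
  out <- do.call(rbind, lapply(names(arms), function(arm) {
    n <- arms[[arm]]
    p <- config[[arm]]
    draw <- function(par) if (par[2] == 0) rep(par[1], n) else stats::rnorm(n, par[1], par[2])
    female <- stats::runif(n) < p$female
    caucasian <- stats::runif(n) < p$caucasian
    eth <- ifelse(caucasian, "caucasian",
                  ifelse(stats::runif(n) < 0.5, "afro_caribbean", "asian_indian"))
    age <- draw(p$age)
    bmi <- pmax(draw(p$bmi), 15)
    height <- ifelse(female, 1.62, 1.76)
    weight <- bmi * height^2
    chol <- pmax(draw(p$chol), 2)
    hdl <- pmax(draw(p$hdl), 0.4)
    hdl <- pmin(hdl, chol - 0.1)
    sbp <- pmax(draw(p$sbp), 80)
    hba1c <- pmax(draw(p$hba1c), 4)
    smoker <- stats::runif(n) < p$smoker
    fu <- rtruncnorm(n, config$followup[1], config$followup[2],
                     config$followup_bounds[1], config$followup_bounds[2])
    te <- if (arm == "intensive") config$treatment_effect else
      c(sbp = 0, hba1c = 0, chol = 0)
    noise <- config$measurement_noise
    meas <- function(base, v, frac) {
      shift <- config$secular_change[[v]] * frac + te[[v]]
      nd <- if (noise[[v]] == 0) 0 else stats::rnorm(n, 0, noise[[v]])
      base + shift + nd
    }
    sbp1 <- pmax(meas(sbp, "sbp", 0.5), 80)
    sbp5 <- pmax(meas(sbp, "sbp", 1), 80)
    hba1c1 <- pmax(meas(hba1c, "hba1c", 0.5), 4)
    hba1c5 <- pmax(meas(hba1c, "hba1c", 1), 4)
    chol1 <- pmax(meas(chol, "chol", 0.5), 2)
    chol5 <- pmax(meas(chol, "chol", 1), 2)
    hdl_noise <- function() if (noise[["hdl"]] == 0) 0 else stats::rnorm(n, 0, noise[["hdl"]])
    hdl1 <- pmin(pmax(hdl + hdl_noise(), 0.4), chol1 - 0.1)
    hdl5 <- pmin(pmax(hdl + hdl_noise(), 0.4), chol5 - 0.1)
    smoker1 <- smoker & stats::runif(n) >= config$quit_prob[1]
    smoker5 <- smoker1 & stats::runif(n) >= config$quit_prob[2]
    data.frame(arm = arm,
               centre = ifelse(stats::runif(n) < config$centre_prop_cambridge,
                               "Cambridge", "Leicester"),
               age = age, female = female, ethnicity = eth,
               height = height, weight = weight, bmi = bmi,
               smoker_y0 = as.numeric(smoker),
               chol_y0 = chol, hdl_y0 = hdl, sbp_y0 = sbp, hba1c_y0 = hba1c,
               smoker_y1 = as.numeric(smoker1), chol_y1 = chol1,
               hdl_y1 = hdl1, sbp_y1 = sbp1, hba1c_y1 = hba1c1,
               smoker_y5 = as.numeric(smoker5), chol_y5 = chol5,
               hdl_y5 = hdl5, sbp_y5 = sbp5, hba1c_y5 = hba1c5,
               followup_years = fu,
               stringsAsFactors = FALSE)
  }))
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Simulate first cardiovascular events over follow-up
#'
#' Draws each patient's time to first cardiovascular event from an
#' exponential distribution at the arm's constant hazard (routine hazard
#' times the hazard ratio in the intensive arm), censored at the patient's
#' follow-up. Event types are sampled from the configured mix; only
#' cardiovascular death is fatal.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param cvd_hazard_routine Routine-arm hazard, events per person-year.
#' @param hazard_ratio Intensive:routine hazard ratio.
#' @param seed Integer seed.
#' @param event_mix Named probabilities over event types.
#' @return The cohort with columns `event_type` (`NA` if censored),
#'   `event_time` (years, `NA` if censored), `event_year` (1-based year
#'   index), `event_fatal` and `alive` appended.
#' @export
simulate_trial_events <- function(cohort, cvd_hazard_routine = 0.0159,
                                  hazard_ratio = 0.83, seed = 1L,
                                  event_mix = c(mi = 0.30, stroke = 0.25,
                                                revascularization = 0.25,
                                                amputation = 0.05,
                                                cvd_death = 0.15)) {
  if (cvd_hazard_routine <= 0 || hazard_ratio <= 0) {
    stop("cohort configuration error: hazards must be > 0")
  }
  if (is.null(cohort$followup_years)) stop("follow-up must be assigned")
  set.seed(seed)
  n <- nrow(cohort)
  rate <- ifelse(cohort$arm == "intensive",
                 cvd_hazard_routine * hazard_ratio, cvd_hazard_routine)
  t_event <- stats::rexp(n, rate)
  occurred <- t_event <= cohort$followup_years
  type <- rep(NA_character_, n)
  type[occurred] <- sample(names(event_mix), sum(occurred), replace = TRUE,
                           prob = event_mix)
  cohort$event_type <- type
  cohort$event_time <- ifelse(occurred, t_event, NA_real_)
  cohort$event_year <- ifelse(occurred, pmax(1L, ceiling(t_event)), NA_integer_)
  cohort$event_fatal <- !is.na(type) & type == "cvd_death"
  cohort$alive <- !cohort$event_fatal
  cohort
}

#' Recover the arm hazard ratio from simulated events
#'
#' Calibration check for the event generator: fits a proportional-hazards
#' model of time to first cardiovascular event on treatment arm, with
#' censoring at each patient's follow-up, and returns the estimated
#' intensive:routine hazard ratio with its standard error. On a large
#' simulated cohort the estimate recovers the generating ratio.
#'
#' @param cohort Cohort with events from [simulate_trial_events()].
#' @return List with `hr`, `log_hr`, `se_log_hr` and `ci` (95% for the HR).
#' @export
recover_hazard_ratio <- function(cohort) {
  time <- ifelse(is.na(cohort$event_time), cohort$followup_years,
                 cohort$event_time)
  status <- as.integer(!is.na(cohort$event_time))
  arm <- factor(cohort$arm, levels = c("routine", "intensive"))
  fit <- survival::coxph(survival::Surv(time, status) ~ arm)
  b <- stats::coef(fit)[["armintensive"]]
  se <- sqrt(stats::vcov(fit)[1, 1])
  list(hr = exp(b), log_hr = b, se_log_hr = se,
       ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se))
}

#' Observed first-event incidence per 1000 person-years
#'
#' Person-time is accrued to the first event or censoring at follow-up;
#' the rate is first events divided by person-years, scaled by 1000.
#'
#' @param cohort Cohort with events from [simulate_trial_events()].
#' @return List with `rate_per_1000py`, `events`, `person_years` and the
#'   Poisson standard error `se_per_1000py`.
#' @export
event_incidence <- function(cohort) {
  time <- ifelse(is.na(cohort$event_time), cohort$followup_years,
                 cohort$event_time)
  events <- sum(!is.na(cohort$event_time))
  py <- sum(time)
  list(rate_per_1000py = 1000 * events / py, events = events,
       person_years = py, se_per_1000py = 1000 * sqrt(events) / py)
}

#' Imputable measurement columns of a cohort
#' @param cohort A cohort data frame.
#' @return Character vector of column names.
#' @export
imputable_columns <- function(cohort) {
  intersect(c("weight", "height",
              paste0(rep(c("smoker", "chol", "hdl", "sbp", "hba1c"), each = 3),
                     "_y", rep(c(0, 1, 5), 5))),
            names(cohort))
}

#' Set cells missing completely at random
#'
#' Each targeted cell is independently set to `NA` with probability `rate`
#' (MCAR). The unmodified input is returned alongside as the withheld truth.
#'
#' @param cohort A cohort data frame.
#' @param rate Missingness probability in `[0, 1)`.
#' @param variables Columns to target; defaults to all imputable measurement
#'   columns.
#' @param seed Integer seed.
#' @return A list with `cohort` (holes punched) and `truth` (original).
#' @export
inject_missingness <- function(cohort, rate, variables = imputable_columns(cohort),
                               seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("missing rate must lie in [0, 1)")
  }
  truth <- cohort
  if (rate > 0) {
    set.seed(seed)
    for (v in variables) {
      holes <- stats::runif(nrow(cohort)) < rate
      cohort[[v]][holes] <- NA
    }
  }
  list(cohort = cohort, truth = truth)
}

#' Write a cohort panel as CSV with a sidecar parameter file
#'
#' Missing cells are encoded as empty fields. The sidecar
#' (`<path>.params.yaml`) records every generation parameter and the seed so
#' a run can be reproduced byte-for-byte.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @param config The [cohort_config()] used (optional).
#' @param seed The generation seed (optional).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL, seed = attr(cohort, "seed")) {
  num <- vapply(cohort, is.numeric, logical(1))
  cohort[num] <- lapply(cohort[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 10, format = "g"))
  })
  utils::write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(config)) {
    side <- unclass(config)
    side$seed <- seed
    yaml::write_yaml(side, paste0(path, ".params.yaml"))
  }
  invisible(path)
}

#' Read a cohort panel written by [write_cohort()]
#' @param path CSV path.
#' @return Cohort data frame (empty fields become `NA`).
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
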