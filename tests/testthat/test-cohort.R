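test_that("per-arm sample moments match the configured distributions", {
  co <- generate_cohort(cohort_config(), seed = 101)
  routine <- co[co$arm == "routine", ]
  intensive <- co[co$arm == "intensive", ]
  expect_equal(nrow(routine), 511)
  expect_equal(nrow(intensive), 513)
  se <- 7.5 / sqrt(511)
  expect_lt(abs(mean(routine$age) - 60.1), 3 * se)
  expect_lt(abs(mean(intensive$age) - 61.1), 3 * 7.2 / sqrt(513))
  expect_lt(abs(mean(routine$female) - 0.407),
            3 * sqrt(0.407 * 0.593 / 511))
  expect_lt(abs(mean(routine$sbp_y0) - 143.1), 3 * 19.4 / sqrt(511))
  expect_lt(abs(mean(routine$bmi) - 33.0), 3 * 5.9 / sqrt(511))
  expect_lt(abs(sd(routine$hba1c_y0) - 1.7), 0.3)
  # follow-up: truncated normal around 5.0 (sd 1.1), bounded in [1, 9]
  expect_true(all(co$followup_years >= 1 & co$followup_years <= 9))
  expect_lt(abs(mean(co$followup_years) - 5.0), 3 * 1.1 / sqrt(nrow(co)))
  # HDL never exceeds total cholesterol at any measurement year
  for (yr in c(0, 1, 5)) {
    expect_true(all(co[[paste0("hdl_y", yr)]] <=
                      co[[paste0("chol_y", yr)]]))
  }
  # BMI consistency: weight derived from height and BMI
  expect_equal(co$weight / co$height^2, co$bmi)
})

test_that("zero spread collapses continuous variables to their means", {
  cfg <- cohort_config(n_routine = 30, n_intensive = 30)
  for (arm in c("routine", "intensive")) {
    for (v in c("age", "bmi", "chol", "hdl", "sbp", "hba1c")) {
      cfg[[arm]][[v]][2] <- 0
    }
  }
  cfg$measurement_noise[] <- 0
  cfg$followup[2] <- 0
  co <- generate_cohort(cfg, seed = 5)
  routine <- co[co$arm == "routine", ]
  expect_equal(unique(routine$age), 60.1)
  expect_equal(unique(routine$sbp_y0), 143.1)
  expect_equal(unique(routine$hba1c_y0), 7.3)
  expect_equal(unique(co$followup_years), 5.0)
  # intensive-arm year-5 measurement shows exactly the configured shifts
  intensive <- co[co$arm == "intensive", ]
  expect_equal(unique(intensive$sbp_y5), 142.0 - 4.5 - 1.5)
  expect_equal(unique(routine$sbp_y5), 143.1 - 4.5)
})

test_that("treatment effect shifts intensive-arm follow-up measurements", {
  co <- generate_cohort(cohort_config(n_routine = 3000, n_intensive = 3000),
                        seed = 9)
  gap <- function(v) {
    mean(co[[v]][co$arm == "intensive"]) - mean(co[[v]][co$arm == "routine"])
  }
  baseline_gap <- 142.0 - 143.1
  expect_lt(abs(gap("sbp_y5") - (baseline_gap - 1.5)), 3 * 20 * sqrt(2 / 3000))
  expect_lt(abs(gap("hba1c_y5") - (0 - 0.06)), 3 * 1.8 * sqrt(2 / 3000))
})

test_that("the generator is deterministic given config and seed", {
  cfg <- cohort_config(n_routine = 40, n_intensive = 40, missing_rate = 0)
  a <- generate_cohort(cfg, seed = 77)
  b <- generate_cohort(cfg, seed = 77)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1, config = cfg, seed = 77)
  write_cohort(b, f2, config = cfg, seed = 77)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(file.exists(paste0(f1, ".params.yaml")))
  back <- read_cohort(f1)
  expect_equal(back$sbp_y0, a$sbp_y0, tolerance = 1e-8)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_routine = 0), "configuration error")
  expect_error(cohort_config(cvd_hazard_routine = -0.1), "configuration error")
  bad <- cohort_config(); bad$routine$age[2] <- -1
  expect_error(validate_cohort_config(bad), "configuration error")
  bad2 <- cohort_config(); bad2$missing_rate <- 1.2
  expect_error(validate_cohort_config(bad2), "configuration error")
})

test_that("event times are exponential at the configured hazard", {
  # long follow-up so no censoring: Kolmogorov-Smirnov against the
  # exponential with the generating rate
  cfg <- cohort_config(n_routine = 4000, n_intensive = 2,
                       followup = c(400, 0), followup_bounds = c(300, 500))
  co <- generate_cohort(cfg, seed = 3)
  co <- simulate_trial_events(co, cvd_hazard_routine = 0.0159,
                              hazard_ratio = 0.83, seed = 4)
  times <- co$event_time[co$arm == "routine"]
  expect_gt(suppressWarnings(
    stats::ks.test(times, stats::pexp, rate = 0.0159)$p.value), 0.01)
})

test_that("arm incidences agree under a null hazard ratio", {
  cfg <- cohort_config(n_routine = 8000, n_intensive = 8000)
  co <- generate_cohort(cfg, seed = 21)
  co <- simulate_trial_events(co, cvd_hazard_routine = 0.0159,
                              hazard_ratio = 1.0, seed = 22)
  ri <- event_incidence(co[co$arm == "routine", ])
  ii <- event_incidence(co[co$arm == "intensive", ])
  expect_lt(abs(ri$rate_per_1000py - ii$rate_per_1000py),
            3 * sqrt(ri$se_per_1000py^2 + ii$se_per_1000py^2))
  hr <- recover_hazard_ratio(co)
  expect_lt(abs(hr$log_hr), 3 * hr$se_log_hr)
})

test_that("only cardiovascular death is fatal and events respect follow-up", {
  co <- generate_cohort(cohort_config(n_routine = 2000, n_intensive = 2000),
                        seed = 31)
  co <- simulate_trial_events(co, seed = 32)
  got <- !is.na(co$event_type)
  expect_true(all(co$event_time[got] <= co$followup_years[got]))
  expect_identical(co$event_fatal, !is.na(co$event_type) &
                     co$event_type == "cvd_death")
  expect_true(all(co$event_year[got] >= 1))
  expect_setequal(unique(co$event_type[got]),
                  c("mi", "stroke", "revascularization", "amputation",
                    "cvd_death"))
  expect_error(simulate_trial_events(co, cvd_hazard_routine = 0),
               "hazards must be")
})

test_that("MCAR injection hits the target rate and keeps a truth copy", {
  co <- generate_cohort(cohort_config(n_routine = 4000, n_intensive = 4000),
                        seed = 41)
  out <- inject_missingness(co, rate = 0.2, variables = "hba1c_y0", seed = 42)
  frac <- mean(is.na(out$cohort$hba1c_y0))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(co)))
  expect_identical(out$truth, co)
  expect_false(anyNA(out$cohort$sbp_y0))
  # rate 0 leaves the cohort untouched; rate 1 is rejected
  expect_identical(inject_missingness(co, 0)$cohort, co)
  expect_error(inject_missingness(co, 1), "rate")
  # rate 0.5 on all imputable variables marks every variable
  all_half <- inject_missingness(co, 0.5, seed = 43)$cohort
  for (v in imputable_columns(co)) expect_true(anyNA(all_half[[v]]))
})
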