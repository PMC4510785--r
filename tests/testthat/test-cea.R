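test_that("ICER classification covers every sign combination", {
  expect_equal(icer(1395, 0.0465),
               list(class = "finite", value = 30000))
  expect_equal(icer(935, -0.0040)$class, "dominated")
  expect_equal(icer(285, 0)$class, "infinite")
  expect_equal(icer(-50, 0.01)$class, "dominant")
  expect_equal(icer(0, 0)$class, "indifferent")
  # exhaustive sweep of the plane
  for (dc in c(-10, 0, 10)) {
    for (dq in c(-0.1, 0, 0.1)) {
      cls <- icer(dc, dq)$class
      expect_identical(cls == "dominated", dc > 0 && dq < 0)
      expect_identical(cls == "infinite", dq == 0 && dc > 0)
      if (dc < 0 && dq > 0) expect_identical(cls, "dominant")
      if (cls == "finite") expect_equal(icer(dc, dq)$value, dc / dq)
    }
  }
})

test_that("with constant covariates the arm coefficient is the raw mean difference", {
  d <- flat_cohort(25)
  d$centre <- "Cambridge"; d$age <- 60; d$female <- TRUE; d$hba1c_y0 <- 7
  set.seed(1)
  d$cost <- 500 + 100 * (d$arm == "intensive") + rnorm(nrow(d), 0, 20)
  d$qaly <- 3.6 + rnorm(nrow(d), 0, 0.05)
  ai <- adjusted_increment(d)
  raw <- mean(d$cost[d$arm == "intensive"]) - mean(d$cost[d$arm == "routine"])
  expect_equal(ai$cost$estimate, raw)
})

test_that("a known injected arm effect is recovered within its CI", {
  set.seed(8)
  n <- 4000
  d <- data.frame(arm = rep(c("routine", "intensive"), each = n / 2),
                  centre = sample(c("Cambridge", "Leicester"), n, TRUE),
                  age = rnorm(n, 60, 7), female = runif(n) < 0.4,
                  hba1c_y0 = rnorm(n, 7.3, 1.7))
  d$cost <- 2000 + 300 * (d$arm == "intensive") + 10 * d$age +
    50 * d$female + rnorm(n, 0, 400)
  d$qaly <- 3.6 + 0.02 * (d$arm == "intensive") - 0.01 * (d$hba1c_y0 - 7.3) +
    rnorm(n, 0, 0.3)
  ai <- adjusted_increment(d)
  expect_gt(300, ai$cost$ci[1]); expect_lt(300, ai$cost$ci[2])
  expect_gt(0.02, ai$qaly$ci[1]); expect_lt(0.02, ai$qaly$ci[2])
  expect_equal(ai$icer$class, "finite")
})

test_that("adjusted increments equal the normal-equations oracle", {
  set.seed(12)
  for (rep in 1:4) {
    n <- 60
    d <- data.frame(arm = rep(c("routine", "intensive"), each = n / 2),
                    centre = sample(c("Cambridge", "Leicester"), n, TRUE),
                    age = rnorm(n, 60, 7), female = runif(n) < 0.4,
                    hba1c_y0 = rnorm(n, 7.3, 1.7))
    d$cost <- rnorm(n, 1000, 300)
    d$qaly <- rnorm(n, 3, 0.4)
    X <- cbind(1, d$arm == "intensive", d$centre == "Leicester", d$age,
               d$female, d$hba1c_y0)
    expect_equal(adjusted_increment(d)$cost$estimate,
                 ols_oracle(d$cost, X)[2], tolerance = 1e-10)
  }
})

test_that("degenerate outcomes and designs are reported", {
  d <- flat_cohort(10)
  d$cost <- 0; d$qaly <- 0
  ai <- adjusted_increment(d)
  expect_equal(ai$cost$estimate, 0)
  expect_lt(diff(ai$cost$ci), 1e-8)
  # a covariate collinear with the arm indicator names itself
  d2 <- flat_cohort(10)
  d2$centre <- ifelse(d2$arm == "routine", "Cambridge", "Leicester")
  d2$cost <- rnorm(nrow(d2)); d2$qaly <- rnorm(nrow(d2))
  expect_error(adjusted_increment(d2), "collinear.*centre")
})

test_that("an arm-neutral cohort yields null increments", {
  co <- flat_cohort(40)
  tab <- the_tables
  ct <- cumulative_table(co, tab, horizons = 1:5,
                         intervention_schedule = rep(0, 5))
  expect_true(all(abs(ct$delta_cost) < 1e-8))
  expect_true(all(abs(ct$delta_qaly) < 1e-8))
  # per-arm means equal the event-free annuity
  expect_equal(ct$mean_cost_routine[5], 494.5 * annuity(5, 0.035))
})

test_that("a year-1 intervention charge appears as the year-1 increment", {
  co <- flat_cohort(40)
  ct <- cumulative_table(co, the_tables, horizons = 1:3,
                         intervention_schedule = c(285, 0, 0, 0, 0))
  expect_equal(ct$delta_cost[1], 285)
  expect_equal(ct$delta_cost[3], 285)
  expect_equal(ct$icer_class[1], "infinite")
})

test_that("discounting never increases cumulative totals", {
  co <- flat_cohort(20)
  co$event_type[3] <- "mi"; co$event_time[3] <- 1.5
  co$event_year[3] <- 2L; co$event_fatal[3] <- FALSE
  sched <- intervention_cost_schedule()
  d35 <- cumulative_table(co, the_tables, 1:5, rate = 0.035,
                          intervention_schedule = sched)
  d0 <- cumulative_table(co, the_tables, 1:5, rate = 0,
                         intervention_schedule = sched)
  expect_true(all(d35$mean_cost_routine <= d0$mean_cost_routine))
  expect_true(all(d35$mean_qaly_intensive <= d0$mean_qaly_intensive))
})

test_that("patients contribute only to horizons within their follow-up", {
  co <- flat_cohort(30, followup = 5)
  co$followup_years[co$id <= 10] <- 3.2
  ct <- cumulative_table(co, the_tables, horizons = 1:5,
                         intervention_schedule = rep(0, 5))
  expect_equal(ct$n_routine[1] + ct$n_intensive[1], 60)
  expect_equal(ct$n_routine[4] + ct$n_intensive[4], 50)
  expect_warning(
    cumulative_table(flat_cohort(10, followup = 2), the_tables, horizons = 3,
                     intervention_schedule = rep(0, 5)),
    "follow-up support")
})

test_that("cumulative valuation is non-decreasing in horizon for every patient", {
  set.seed(33)
  for (rep in 1:6) {
    k <- sample(0:2, 1)
    ev <- if (k == 0) NULL else
      data.frame(condition = sample(c("mi", "stroke", "cvd_death"), k),
                 year = sample(1:6, k), fatal = FALSE)
    if (!is.null(ev) && "cvd_death" %in% ev$condition) {
      ev$fatal[ev$condition == "cvd_death"] <- TRUE
      ev <- ev[!duplicated(ev$fatal) | !ev$fatal, ]
    }
    a <- accumulate(ev, 8, 0.035, the_tables)
    expect_true(all(a$yearly$cost >= 0))
    expect_true(all(a$yearly$utility >= 0))
    expect_true(all(diff(cumsum(a$yearly$cost * a$yearly$weight)) >= 0))
  }
})

test_that("the default intervention schedule sums to the per-person cost", {
  sched <- intervention_cost_schedule()
  tot <- ledger_totals(read_cost_items())
  expect_equal(sum(sched), tot$per_person)
  expect_equal(length(sched), 5L)
})
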