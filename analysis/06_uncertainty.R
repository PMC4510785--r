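#!/usr/bin/env Rscript
# Stage 6: decision uncertainty on the 30-year results.
#
# From the bootstrap draws of stage 5: cost-effectiveness plane clouds and
# acceptability curves under three intervention delivery costs (the base
# per-person cost and the two cheaper-delivery scenarios), the threshold
# delivery cost at which the 30-year ICER hits 30,000 GBP/QALY, scenario
# point-estimate ICERs, and a one-way tornado (unit treatment costs and
# utility decrements +/-10%, discount rate 0%/5%) re-running a reduced
# microsimulation with identical seeds under each perturbation.

library(diabcea)

draws30 <- read.csv("results/bootstrap_draws.csv")
draws30 <- draws30[draws30$horizon == 30, ]
inc <- read.csv("results/longterm_increments.csv")
base <- inc[inc$horizon == 30, ]
totals <- ledger_totals(read_cost_items())
c0 <- totals$per_person
scenarios <- c(round(c0), 750, 500)

## CE plane and CEAC under the three delivery costs
plane <- do.call(rbind, lapply(scenarios, function(cs)
  ce_plane(shift_draws(draws30, c0 = round(c0), scenario_cost = cs))))
write.csv(plane, "results/ce_plane.csv", row.names = FALSE)
curves <- do.call(rbind, lapply(scenarios, function(cs) {
  d <- shift_draws(draws30, c0 = round(c0), scenario_cost = cs)
  cbind(ceac(d), scenario = d$scenario[1])
}))
write.csv(curves, "results/ceac.csv", row.names = FALSE)
for (cs in scenarios) {
  cc <- curves[curves$scenario == paste0("GBP ", cs), ]
  cat(sprintf("P(cost-effective) at delivery cost %4d: %.1f%% (20k), %.1f%% (30k)\n",
              cs, 100 * cc$probability[cc$lambda == 20000],
              100 * cc$probability[cc$lambda == 30000]))
}

## threshold and scenario ICERs from this run's own 30-year point estimates
if (base$delta_qaly > 0) {
  thr <- threshold_cost(base$delta_cost, base$delta_qaly, c0, 30000)
  cat(sprintf("delivery cost for a 30,000 GBP/QALY ICER: %.0f GBP\n", thr))
  sc <- scenario_icers(base$delta_cost, base$delta_qaly, c0, scenarios)
  print(sc, digits = 5)
  write.csv(sc, "results/scenario_icers.csv", row.names = FALSE)
} else {
  cat("30-year incremental QALYs not positive; no finite threshold cost\n")
}

## tornado on a reduced re-run: same seeds, perturbed valuation/discounting
set.seed(20261002L)
stacked <- read_cohort("results/cohort_imputed.csv")
one_imp <- stacked[stacked$imputation == 1, ]
sub <- one_imp[sort(sample.int(nrow(one_imp), 300)), ]
eqs <- read_risk_equations()
upfront <- local({
  pc <- totals$per_person_components
  c(pc[["delivery"]] + pc[["extra_consultations"]] / 3,
    rep(pc[["extra_consultations"]] / 3, 2))
})
evaluate <- function(cost_factor, decrement_factor, discount_rate) {
  cfg <- sim_config(horizon = 30, inner_loops = 100, bootstraps = 0,
                    horizons = 30, seed = 20261001L,
                    discount_rate = discount_rate,
                    intervention_annual_cost = 262.5,
                    intervention_upfront = upfront,
                    cost_factor = cost_factor,
                    decrement_factor = decrement_factor)
  ex <- cohort_extrapolate(sub, eqs, cfg)
  list(delta_cost = ex$increments[["30"]]$cost$estimate,
       delta_qaly = ex$increments[["30"]]$qaly$estimate)
}
tor <- one_way_tornado(evaluate)
print(tor, digits = 5)
write.csv(tor, "results/tornado.csv", row.names = FALSE)
cat("written: results/{ce_plane,ceac,scenario_icers,tornado}.csv\n")
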