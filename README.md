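# diabcea

Trial-based and model-based cost-utility analysis of early **intensive
multifactorial treatment versus routine care in screen-detected type 2
diabetes**, from a UK payer (NHS) perspective. The package is aimed at
health economists and methodologists who want the full analytic pipeline of
such an evaluation as tested, reusable code: intervention micro-costing,
within-trial cost/QALY accumulation, covariate-adjusted incremental
estimation, multivariate-normal multiple imputation, a UKPDS-style
patient-level outcomes microsimulation for 10–30-year extrapolation, and
bootstrap/threshold/one-way uncertainty analysis.

Patient-level data from the motivating trial are not public, so the
package runs entirely on (a) the trial's printed parameter tables, shipped
as plain-CSV fixtures (the itemized intervention cost build-up,
per-condition unit costs and utility decrements, per-arm baseline
characteristics), and (b) synthetic cohorts from a generator that
reproduces the statistical structure those tables imply — two arms of
511/513 patients, first-cardiovascular-event hazard 15.9 per 1000
person-years in routine care with a hazard ratio of 0.83, follow-up
centred on 5.0 (sd 1.1) years, and configurable MCAR missingness.

## The model in brief

* **Costing.** Each resource line resolves as `unit_rate × quantity ×
  multiplicity` (or an internal-accounting lump sum); multi-year streams
  discount year *t* by `(1 + r)^-(t-1)` at *r* = 3.5%/year.
* **Valuation.** A patient-year costs the base diabetes cost plus additive
  event-year and subsequent-year complication costs; utility is
  `1 − 0.220 − Σ decrements`, floored at 0, with the same decrement in the
  event year and every later year.
* **Incremental estimation.** OLS of per-patient cost and QALYs on
  treatment arm, centre, age at diagnosis, sex and baseline HbA1c; the arm
  coefficients give ΔC and ΔQ, and `ICER = ΔC/ΔQ` with dominance
  classification for the degenerate sign combinations.
* **Imputation.** Data-augmentation MCMC under a multivariate normal
  (Jeffreys prior), m = 5, smoking thresholded from the latent scale,
  HDL repaired below total cholesterol; Rubin's rules pool estimates with
  total variance `W + (1 + 1/m)B`.
* **Microsimulation.** Annual cycle per patient: deterministic risk-factor
  paths (lagged linear equations, observed years 0/1/5 override), annual
  event probabilities through logistic or Weibull-increment links, death
  drawn last, valuation plus continuing intensive-arm prescription costs,
  inner-loop means per patient, patient-level bootstrap for uncertainty.
  The shipped coefficient set is **synthetic** (the licensed published
  model's coefficients are not redistributable) — structure is validated,
  absolute long-term levels are illustrative.
* **Decision uncertainty.** CEAC as `P(λ·ΔQ − ΔC > 0)` over bootstrap
  draws; threshold delivery cost `c* = c0 − (ΔC − λ·ΔQ)`; scenario ICERs
  at alternative delivery costs; one-way tornado over unit costs (±10%),
  decrements (±10%) and discount rate (0–5%).

## Worked example

```r
library(diabcea)

## the intervention's five-year cost, from the packaged itemized table
print(ledger_totals(read_cost_items()))
#> Intervention cost totals (GBP, rounded to nearest pound)
#>   delivery                173,895
#>   extra_consultations     190,010
#>   extra_treatments        139,069
#>   total                   502,974
#>   per person: 980  (components: 339 + 370 + 271)
#>   Cambridge: total 432,815, per person 958 (n = 452)
#>   Leicester: total 70,159, per person 1150 (n = 61)

## at what delivery cost does the 30-year ICER reach 30,000 GBP/QALY?
## (published 30-year adjusted increments: 1745 GBP, 0.0465 QALYs)
threshold_cost(1745, 0.0465, c0 = 981, lambda = 30000)
#> [1] 631
scenario_icers(1745, 0.0465, c0 = 981)
#>   scenario_cost delta_cost  icer
#> 1           981       1745 37527
#> 2           750       1514 32559
#> 3           500       1264 27183

## a synthetic trial cohort, calibrated to the published event structure
cfg <- cohort_config(n_routine = 5000, n_intensive = 5000)
co  <- generate_cohort(cfg, seed = 1)
co  <- simulate_trial_events(co, seed = 2)
event_incidence(co[co$arm == "routine", ])$rate_per_1000py
#> [1] 15.85855
recover_hazard_ratio(co)$hr
#> [1] 0.9016393  # 95% CI 0.78-1.05 at this sample size
```

The totals reproduce the published build-up exactly (subtotals £173,895 /
£190,010 / £139,069, total £502,974); the per-person components are £339
delivery and £370 consultations over the 513 intensive-arm participants;
£631 is the published break-even delivery cost at £30,000/QALY. The
synthetic cohort recovers the routine-arm rate of 15.9 per 1000
person-years, and the proportional-hazards fit recovers the generating
hazard ratio within Monte-Carlo error (tightly so at the larger sample
sizes the acceptance checks use).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on a synthetic
cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort + events + MCAR holes
Rscript analysis/02_intervention_costing.R
Rscript analysis/03_within_trial_cea.R    # years 1-5 cumulative table
Rscript analysis/04_impute.R              # m = 5 completed panels
Rscript analysis/05_extrapolate.R         # 10/20/30-year microsimulation
Rscript analysis/06_uncertainty.R         # CE plane, CEAC, tornado, thresholds
```

Stage 5 is the expensive one (a few minutes at the shipped problem
sizes). Stage 6 prints acceptability probabilities at £20,000/£30,000 per
QALY for delivery costs £980/£750/£500 and writes plot-ready CSVs
(`ce_plane.csv`, `ceac.csv`, `tornado.csv`); `plot_ce_plane()`,
`plot_ceac()` and `plot_tornado()` render them with ggplot2.

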