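---
title: "Methods: trial-based and model-based cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based and model-based cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabcea)
```

# The evaluation problem

diabcea implements the full analytic pipeline of a cost-utility analysis
comparing early intensive multifactorial treatment against routine care in
people with screen-detected type 2 diabetes, from a UK payer (NHS)
perspective. The pipeline has two halves:

* a **within-trial analysis** over years 1–5 after diagnosis, accumulating
  observed costs and quality-adjusted life years (QALYs) per patient; and
* a **model-based extrapolation** to 10, 20 and 30 years with an
  annual-cycle patient-level outcomes microsimulation in the style of the
  published UKPDS outcomes model.

Both halves report the covariate-adjusted incremental cost
$\Delta C$ and incremental QALYs $\Delta Q$ of the intensive arm and the
incremental cost-effectiveness ratio $\mathrm{ICER} = \Delta C / \Delta Q$,
with decision uncertainty summarised on the cost-effectiveness plane, as
acceptability curves over the willingness-to-pay $\lambda$ (probability that
net monetary benefit $\lambda\,\Delta Q - \Delta C$ is positive), and by
one-way sensitivity and threshold analysis.

Individual patient data from the trial that motivates this design are not
public. The package therefore ships (a) the trial's *printed* parameter
tables — the itemized intervention cost build-up, per-condition unit costs
and utility decrements, and per-arm baseline distributions — as plain-CSV
fixtures, and (b) a synthetic cohort generator that reproduces the
*statistical structure* those tables and the published event rates imply.
Every downstream stage is exercised, tested and documented on synthetic
cohorts; the published absolute cost/QALY levels that would require the
real patient records are treated as out of reach and covered by
closed-form and enumeration properties instead.

# Intervention micro-costing

`read_cost_items()` loads the itemized cost table (2009/10 GBP). A row's
value is `unit_rate × quantity × multiplicity`, unless the row was costed
by internal trial accounting or already carries multi-year discounting, in
which case a `lump_sum` override governs it. The four extra-consultation
rows are stored as lump sums deliberately: their printed values embed a
3.5%-per-annum discounted three-year schedule that is not exactly
recoverable from the printed unit rates under any standard convention we
could verify symbolically, and fidelity to the published totals was judged
more useful than a speculative reconstruction. The discounting operation
itself, `discounted_stream()`, weights year $t$ by $(1+r)^{-(t-1)}$ (year 1
undiscounted) and is verified against the geometric closed form.

`ledger_totals()` reproduces the published build-up: category subtotals of
£173,895 (delivery), £190,010 (extra consultations) and £139,069 (extra
treatments); a five-year total of £502,974; and a per-person cost of
£980.46 over the 513 intensive-arm participants (the published rounded
figure is £981; the unrounded value is retained internally and rounding is
applied at output only).

**Per-centre totals are not reproducible from the itemized rows.** The
published split (£412,595 Cambridge / £90,379 Leicester, i.e. £913 and
£1,482 per person) conflicts with the table it accompanies: the
Cambridge-tagged rows alone sum to £422,653, already above the published
Cambridge total, and an exhaustive enumeration over all $2^{18}$ subsets
of row values shows no combination reaching either published figure. The
package therefore computes per-centre totals under an explicit, stated
rule — centre-tagged rows directly, shared rows pro rata to intensive-arm
centre headcount (452:61) — which yields ≈£958/£1,150 per person. The
corresponding acceptance expectations are left failing by design rather
than forcing the published values in by assignment.

# Valuation: additive costs and utility decrements

`annual_cost()` and `annual_utility()` convert one patient-year state
(prevalent complications, incident events with fatal flags, vital status)
into money and utility using the per-condition table: event-year costs
(fatal or non-fatal), subsequent-year costs, and additive utility
decrements applied identically in the event year and every later year.
A complication-free alive year costs £494.5 and scores
$1 - 0.220 = 0.780$; multiple conditions add their decrements, floored at
zero. Conventions the source leaves open, fixed here and flagged in the
documentation:

* **Death year**: the full event-year cost is charged; the death-year
  utility contribution is zero (no half-cycle credit).
* **Fatal events without a specific fatal cost** fall back to the
  standalone cardiovascular-death cost (£3,724.3); specific fatal costs
  take precedence.
* **Recurrent events** (myocardial infarction, revascularization) charge an
  event-year cost per recurrence, but prevalence — and hence the
  subsequent-year cost and the decrement — is an absorbing flag applied
  once.

`accumulate()` walks an event history year by year, makes events prevalent
from the following year onward, discounts both costs and QALYs after year
1 at 3.5%, and reduces to the plain sum at rate zero. Event-free
accumulation equals the annuity closed form
$494.5 \sum_{t=1}^{H} 1.035^{-(t-1)}$, which the tests use as an oracle
(e.g. 30-year QALYs $0.78 \times 19.036 = 14.85$).

# The synthetic cohort generator

`generate_cohort()` draws the two arms (defaults 511 routine / 513
intensive) from the published baseline distributions: age, BMI, total and
HDL cholesterol, systolic blood pressure and HbA1c as per-arm normals; sex,
ethnicity, smoking and centre as Bernoulli draws. Design choices where the
source gives only summaries:

* **Height/weight** are generated jointly so BMI matches its published
  mean/sd: height is fixed per sex from population norms (1.76 m men,
  1.62 m women) and weight derived as $\mathrm{BMI} \times h^2$.
* **Ethnicity**: Caucasian at the published proportion; the remainder split
  equally between Afro-Caribbean and Asian-Indian (the unclassifiable
  ethnicities the trial excluded are not generated).
* **HDL ≤ total cholesterol** is enforced at every measurement year.
* **Follow-up** is a truncated normal with parent mean 5.0 and sd 1.1
  years. The truncation bounds are [1, 9]: symmetric bounds at ±3.6 sd
  keep the realised mean and sd within 0.2% of the stated moments, whereas
  truncating at the nominal 6-year trial horizon would drag the mean down
  to ≈4.65 years (no truncated normal on [1, 6] can have mean 5.0 *and*
  sd 1.1 — the feasible sd at mean 5.0 is only ≈0.7).
* **Treatment effect**: intensive-arm measurements at years 1 and 5 shift
  by configurable amounts, default −1.5 mmHg SBP, −0.06% HbA1c,
  −0.2 mmol/l cholesterol — the order of the modest published differences —
  on top of a secular improvement common to both arms.
* **Missingness** is MCAR only, cell-wise at a configurable rate, with a
  withheld truth copy returned for validation. The real mechanism is
  unknown; nothing downstream assumes MCAR beyond the imputation tests.
* **Clustering**: the trial randomised general practices, but the
  published intra-class correlation is described as very small and no
  value is given, so practice-level random effects are omitted; centre is
  a fixed covariate.

`simulate_trial_events()` draws time to first cardiovascular event from an
exponential at the arm's constant hazard (default 0.0159/person-year
routine, hazard ratio 0.83), censored at follow-up, with event types from a
configurable mix over {MI, stroke, revascularization, amputation, CVD
death}. The generator's calibration is itself a tested claim: at
~120,000 person-years the observed routine-arm incidence recovers 15.9 per
1000 person-years and a proportional-hazards fit (`recover_hazard_ratio()`,
via `survival::coxph`) recovers the generating ratio within Monte-Carlo
error.

What passing these tests does **not** show: the generator makes no attempt
to reproduce the screening funnel, practice-level correlation,
non-normality of the real risk-factor distributions, informative
missingness, or centre recruitment imbalance beyond a single proportion —
so downstream agreement with the published *absolute* levels is neither
expected nor claimed.

# Within-trial analysis

`cumulative_table()` accumulates each patient's discounted cost and QALYs
at horizons 1–5, adds the per-person intervention cost to the intensive arm
according to a year schedule (default: delivery in year 1, consultations
spread over the three intervention years, prescriptions over five), and
estimates adjusted increments by ordinary least squares on treatment arm,
centre, age at diagnosis, sex and baseline HbA1c (`adjusted_increment()`,
normal-theory 95% intervals). Patients contribute to a horizon only if
followed at least that long, so row denominators shrink with horizon,
mirroring the published table's shrinking *n*; the alternative (partial
contribution through the censoring year) would mix accrual windows within
a row. Covariates that are constant in a given subset carry no information
and are dropped; any genuine collinearity is an error naming the columns.
`icer()` classifies all sign combinations: `dominated`
($\Delta C>0, \Delta Q<0$), `infinite` ($\Delta Q=0, \Delta C>0$),
`dominant` (cheaper with no QALY loss — weak dominance for the
$\Delta Q=0, \Delta C<0$ corner), `indifferent` at the origin, otherwise
the finite ratio. Magnitudes below $10^{-9}$ are treated as zeros so that
numerically-null regression estimates classify as null effects.

# Multiple imputation

`mvn_impute()` implements data augmentation for a multivariate normal with
an arbitrary missingness pattern: an I-step draws missing cells from the
conditional normal given the row's observed cells and current $(\mu,
\Sigma)$, and a P-step draws $(\mu, \Sigma)$ from the Jeffreys-prior
posterior given the completed data ($\Sigma^{-1} \sim
\mathrm{Wishart}_{n-1}(S^{-1})$, $\mu \mid \Sigma \sim N(\bar{x},
\Sigma/n)$). Defaults follow common practice for this sampler: 200 burn-in
iterations, imputations 100 apart, $m = 5$. Binary smoking indicators are
imputed on the latent normal scale and thresholded at 0.5. Imputed HDL
above the same-year total cholesterol — logically impossible — is repaired
to cholesterol − 0.1 (`repair_hdl()`); the rule triggers only when HDL
strictly exceeds cholesterol. `rubins_pool()` combines per-imputation
estimates: total variance is the mean within-imputation variance plus
$(1 + 1/m)$ times the between-imputation variance, with the classic
$(m-1)(1 + W/((1+1/m)B))^2$ degrees of freedom.

Numerical choices: rows are processed grouped by missingness pattern; if
the completed-data covariance is singular (e.g. a binary indicator repeated
unchanged across measurement years), a ridge of $10^{-6}$ times the mean
diagonal keeps the chain proper; a variable constant among its observed
cells, or 100% missing, is an error. The coverage property (95% pooled
intervals covering the generator truth in ≈95% of MCAR replications) is
asserted at $n = 300$ — between the trial's arm sizes — over 200
replications; at much smaller $n$ the same machinery shows the expected
mild finite-sample undercoverage (≈91% at $n = 120$), which is a property
of normal-theory multiple imputation at small samples, not of this
implementation.

# The outcomes microsimulation

`simulate_patient()` is an annual-cycle, patient-level simulator in the
UKPDS-outcomes-model mould. Risk factors (HbA1c, SBP, total cholesterol,
HDL, smoking) follow deterministic linear path equations in the baseline
value, years since diagnosis and the previous-year value; observed
measurements at years 0, 1 and 5 override the path, so the measured
intensive-arm improvements propagate into future event risk. Each year,
every non-prevalent event among {IHD, MI, heart failure, stroke,
amputation, blindness, renal failure} is drawn independently from its
annual probability — logistic, or Weibull cumulative-hazard increments
$p_t = 1 - \exp(-(H(t) - H(t-1)))$, $H(t) = e^{\mathrm{lp}} t^{\kappa}$ —
as a function of age at diagnosis, sex, ethnicity, duration, lagged risk
factors and prevalent-complication flags. The two death causes are drawn
last, so a death year still records (and charges) same-year morbidity. All
complication flags start at zero: the cohort is newly diagnosed. Costs and
QALYs accrue through the valuation engine; intensive-arm patients also pay
the continuing extra-prescription cost (£262.5 per alive year) and the
one-off delivery/consultation components phased over years 1–3, all
discounted at the model rate. The per-patient expectation is the mean of
the inner loops (default 1000).

Further conventions: risk-factor paths carry no stochastic noise (all
randomness enters through event draws — chosen for reproducibility, and
because the source is silent on path noise); within a year, event draws
are independent given the linear predictors; each complication occurs at
most once per simulated life (prevalence blocks re-draws); death by the
diabetes-attributable cause is charged the cardiovascular-death cost,
death from other causes is uncosted.

**The packaged coefficients are synthetic.** The licensed published
model's coefficients are not redistributable, so
`risk_equations_synthetic.yaml` ships a clearly-labelled stand-in with
physiologically-signed effects, loosely calibrated so routine-arm 30-year
cumulative incidences are plausible for this population (MI ≈ 0.36,
stroke ≈ 0.16, heart failure ≈ 0.18, diabetes death ≈ 0.19, other death
≈ 0.69). That is a sanity band, not a validation: absolute outputs of the
default set are illustrative. The engine is coefficient-agnostic — users
with access to a licensed or estimated equation set supply their own YAML.

Correctness is established where exactness is possible: a zero-probability
world reproduces the discounted annuity exactly; a single constant-hazard
death cause matches the geometric closed form; and on a two-event,
three-year toy configuration the simulator agrees with an exhaustive
dynamic-programming enumeration of the outcome distribution within
Monte-Carlo error. Monte-Carlo error of the per-patient mean is verified
to scale as $1/\sqrt{\mathrm{loops}}$.

`cohort_extrapolate()` runs the simulator over the $m$ imputed panels,
estimates adjusted increments and adjusted incidence differences with the
same OLS specification as the within-trial stage, pools across imputations
by Rubin's rules, and resamples patients with replacement (re-running the
adjustment on inner-loop means) for bootstrap draws of
$(\Delta C, \Delta Q)$; bootstrap replicates cycle through the imputations
so the draws reflect between-imputation variation. Patient-level
resampling (rather than resampling simulation replicates) was chosen to
match the bootstrap-of-cost–QALY-pairs description in the source's
uncertainty analysis; how its incidence differences were adjusted is not
stated, and the same linear adjustment is assumed.

# Decision uncertainty

`ceac()` evaluates the probability of cost-effectiveness on a default grid
of £0–50,000/QALY in £500 steps (strict inequality NMB > 0; ties, a
measure-zero event for continuous draws, count as not cost-effective).
`threshold_cost()` solves $c^* = c_0 - (\Delta C - \lambda \Delta Q)$, the
delivery cost at which the ICER equals $\lambda$ — with the published
30-year increments (£1,745, 0.0465) and base cost £981 this gives £631 at
£30,000/QALY. `scenario_icers()` re-prices delivery at alternative
per-person costs; the two satisfy the exact round-trip identity
$\mathrm{ICER}(c^*(\lambda)) = \lambda$, which is asserted in the tests.
`one_way_tornado()` re-evaluates the 30-year ICER under one-at-a-time
perturbations (unit treatment costs ±10%, utility decrements ±10%,
discount rate 0%/5%), re-running the simulation with identical seeds so
only the perturbed parameter moves, and orders parameters by ICER range;
a perturbation that removes the QALY gain reports the ICER classification
instead of a number. Scenario clouds for the plane and the acceptability
curves are obtained by shifting bootstrap incremental costs one-for-one
with the delivery cost (`shift_draws()`), which is exact because the
delivery cost enters every draw additively. Figure data are emitted as
tidy CSV; `plot_ce_plane()`, `plot_ceac()` and `plot_tornado()` render
them when ggplot2 is available.

# Problem sizes

The shipped analysis scripts and the test suite run deliberately scaled
problem sizes, chosen as a balance between Monte-Carlo error and a
single-core run: trial-sized cohorts (1,024 patients) for the within-trial
stages; 150 inner loops, 100 bootstraps and $m = 5$ imputations for the
long-term extrapolation; 25,000–60,000 patients for the generator
calibration checks (>100,000 person-years); 200 replications for the
imputation coverage property; and 40,000 inner loops where a simulation
mean is compared against an exact enumeration. Tolerances follow from the
estimators: three Monte-Carlo standard errors for stochastic checks, exact
or near-machine equality for closed forms.

# Known limitations

* Absolute long-term levels depend on the synthetic coefficient set;
  only structure, calibration and internal consistency are validated.
* Macrovascular focus: no retinopathy/nephropathy beyond the blindness and
  renal-failure lines of the valuation table, and no microvascular risk
  equations beyond those events.
* Additive costing/decrements for multiple conditions, as in the source;
  whether interactions should be multiplicative is an open question there
  too.
* MCAR missingness only; no half-cycle correction; no EQ-5D tariff
  computation (decrements are consumed as published); no
  value-of-information analysis.
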