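---
title: "Model structure, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bictcea)
```

## What the model evaluates

`bictcea` compares two diagnostic pathways for adult hospital inpatients
with a clinical suspicion of urinary tract infection (UTI): standard urine
culture, whose susceptibility result arrives on average 48 hours after
admission, and a rapid bacterial impedance cytometry test (BICT) returning
the same information in about 5 hours. Both arms test every patient once;
the turnaround time is the only mechanistic difference between arms (the
test price can also differ, but defaults to parity because the
technology's price is unknown and threshold pricing is out of scope).

The value of the faster result arises entirely through patients whose
pathogen is resistant to the empirical antibiotic and whose prescribing
was inappropriate: they spend less time on a drug that is not working,
which shortens their stay, reduces their cumulative exposure to the
hourly bloodstream-infection (BSI) hazard, and moves their eventual
hospital exit from the higher-mortality "resistant, inappropriately
treated" profile to the appropriate-treatment profile. The model does not
simulate transmission between patients, so any stewardship benefit from
prevented onward spread is excluded and results are conservative in that
respect.

## Markov structure

Patients move between eight health states in discrete one-hour cycles
(`markov_states()`): on admission they are on empirical therapy, either
effective (`EMP_APPROPRIATE`) or not (`EMP_INAPPROPRIATE`); the arriving
result moves resistant patients to effective second-line therapy
(`POST_APPROPRIATE`) with probability equal to the test's sensitivity,
or misses them (`POST_INAPPROPRIATE`); susceptible patients stay on
empirical therapy unless a false-resistant result (1 − specificity)
switches them unnecessarily (`POST_FALSE_RESISTANT`). Every in-hospital
UTI state carries the same hourly BSI hazard; every in-hospital state can
exit to discharge alive (`WELL`) or death (`DEAD`), which are absorbing.

Hourly competing risks are additive within a row and the stay
probability takes the remainder; construction fails loudly if the risks
leaving any state sum above one. The cohort is propagated as continuous
expected mass (a cohort model, not a microsimulation), so results are
deterministic and exactly linear in cohort size — a property the test
suite exploits (`per-patient × N = population`).

The initial split of each stratum's mass uses the product rule: the
prevalence of "resistant *and* inappropriately prescribed" is the
resistance prevalence to that stratum's empirical antibiotic multiplied by
the inappropriate-prescribing proportion, assuming independence. A worked
example in the source literature quotes 1.5% for a 5% × 20% product; the
product (1.0%) is what this package computes, since no alternative
formula is stated.

### Result arrival: deterministic by default

Two arrival mechanisms are implemented (`mode` argument):

* **`deterministic`** (default): the result arrives at exactly
  t = turnaround; the whole empirical population is reallocated once, by a
  linear allocation map. This matches the single-test semantics of the
  pathway being modelled and gives clean analytic checks (for example,
  inappropriate person-time scales exactly linearly with turnaround when
  nobody exits first).
* **`rate`**: a memoryless hourly hazard 1/turnaround, the classical
  Markov rendering of "moving out of the empirical state at a faster
  rate". Because a correctly-susceptible result leaves the patient in
  `EMP_APPROPRIATE`, the memoryless hazard re-exposes susceptible
  patients to the (1 − specificity) false-switch at every arrival — the
  test is implicitly repeated for as long as the patient stays. For long
  stays and short turnarounds this inflates unnecessary second-line
  switching (and its drug costs) far beyond what a single test can do,
  which is why this mode is not the default. It remains available and
  fully tested, and the patient-level oracle reproduces its behaviour
  exactly as specified.

Deterministic arrival rounds the turnaround to the nearest whole cycle
(48 and 5 hours are already integral).

### Propagation methods

`run_cohort(method = "iterate")` propagates mass hour by hour to the
10 000-hour horizon, verifying mass conservation at every cycle
(tolerance 1e-9 relative) and force-discharging (alive, with a message)
any transient mass remaining at the horizon — under default hazards this
residual is far below 1e-6 of the cohort. `method = "analytic"` computes
the identical expectations in closed form from the fundamental matrix
N = (I − Q)⁻¹ of the absorbing chain, splitting the geometric sum at the
turnaround hour in deterministic mode. The two routes agree to 1e-8 in
the test suite; the analytic route is the default for the probabilistic
and one-way sensitivity analyses, where thousands of paired evaluations
are needed.

## Parameters

All inputs live in one YAML configuration
(`system.file("extdata", "parameters.yaml", package = "bictcea")`),
each with a point estimate, units, a source note, and (where uncertainty
is propagated) a distribution. `parameter_audit()` prints the full table.
Key groups:

* **Clinical course.** `bsi_hourly_rate` (per hour, 3.11e-6) is derived
  from a cumulative risk of 1253 BSIs among 280 462 UTI admissions over a
  60-day window via −log(1−p)/(60·24). Mean length of stay is 5 days for
  susceptible/appropriately treated UTI, multiplied by
  `los_ratio_resistant` (1.3) for resistant-inappropriate stays and 12
  days for BSI; constant exit hazards convert means to daily discharge
  probabilities via 1 − exp(−1/LoS), then to hourly. The share of exits
  that are deaths is 0.028 for treated UTI, doubled
  (`mortality_ratio_resistant` = 2) under resistant-inappropriate
  treatment, 0.15 for BSI. Expressing the resistant values as ratios ≥ 1
  guarantees the "resistance never shortens stay" ordering for every
  sampled draw.
* **Test characteristics.** Sensitivity 0.95 and specificity 0.85 to the
  empirical antibiotic, shared by culture and BICT (both Uniform(0.75, 1)
  in the PSA); turnarounds 48 h and 5 h (structural, not sampled).
* **Costs (2022 GBP).** Standard test £15.67 (£4.98 urine test + £10.69
  culture staff/consumables), BICT priced at parity; general ward
  £24.6/h and ICU £85.07/h, blended by the ICU proportion of each state
  class (complicated 0.139, uncomplicated 0, BSI 0.0795) as a cost
  weight rather than a separate ICU state; daily antibiotic costs are
  formulary-derived placeholders. The hourly ward figure is stored
  directly as published rather than re-derived from the per-day cost,
  whose averaging/inflation steps are not fully specified.
* **Health.** Hourly QALY decrements while ill (UTI 3.31e-5/h, BSI
  6.28e-5/h — disutilities of 0.29 and 0.55 spread over a year), and at
  death the discounted remaining quality-adjusted life expectancy at the
  age-band midpoint (ages 40 and 82.5; 43.5 and 7.6 remaining years;
  utility 0.8). Only this mortality loss extends beyond one year, so it
  is the only discounted quantity (3.5%/year annuity with the final
  partial year prorated); within-admission costs and effects are
  undiscounted.
* **Willingness to pay.** £20 000/QALY.

Uncertainty distributions follow the published pattern: uniforms with
±25% bounds where ranges were assumed rather than estimated (the
inappropriate-prescribing proportion uses its literature range
0.20–0.35), and a gamma for the BSI rate. The printed gamma's shape and
scale imply a mean about nine orders of magnitude above the point
estimate — no shape–scale convention reconciles them — so on load the
package keeps the printed shape (the dispersion) and rescales the scale
so the distribution mean equals the point estimate, with a warning. This
keeps the PSA centred on the deterministic model.

Sampling (`sample_parameter_set()`) is seed-deterministic; draws landing
outside a parameter's structural support (e.g. a proportion above 1,
possible when a configured range exceeds the bound) are rejected,
redrawn and counted.

## The synthetic cohort

The original cohort was extracted from restricted national admissions
data, so `build_cohort()` generates a stand-in with the structure the
analysis needs: a configurable total (default 280 462) split across the
four sex–age groups by weights, then 80/10/10 into
uncomplicated/complicated-oral/complicated-IV within each group. The
16–64 male weight is pinned to 17 192/280 462 (a figure quoted from the
source data); the other three weights are synthetic placeholders, skewed
towards 65–100 females consistently with the published ordering of
population-level impacts. Cohort mass is continuous — 17 192 × 0.1 =
1719.2, reported as 1719 only when an integer view is requested
(`cohort_counts_rounded()`, half-up).

What the generator does **not** emulate: between-stratum differences in
length of stay or mortality, catheterised and paediatric/pregnancy
pathways (excluded from scope), seasonal or per-Trust heterogeneity, and
any diagnosis-code logic. Passing tests therefore demonstrate the
*machinery* — conservation, linearity, orderings, closed forms, oracle
agreement — on realistic magnitudes; they do not validate the placeholder
values against real admissions data, and headline numbers will shift
when restricted-source estimates (stratum weights, LoS means, mortality
splits, QALY decrements, drug prices) are transcribed into the
configuration.

## Treatment pathways and scenarios

Regimens are deterministic per stratum: uncomplicated UTI receives oral
nitrofurantoin empirically with pivmecillinam second line; complicated
oral receives cefalexin then co-amoxiclav (the empirical agent for this
pathway is not named alongside the others in the source, so the third
listed prevalence — cefalexin's — is adopted and configurable);
complicated IV receives gentamicin then IV co-amoxiclav. Only resistance
to the *empirical* antibiotic enters the model; second-line resistance is
deliberately not configurable.

Four scenarios are registered declaratively (`scenario_definition()`):
base population (resistance 5/9/13% for
nitrofurantoin/gentamicin/cefalexin), base per-patient (identical, cohort
mass 1), low-trimethoprim (trimethoprim at 5% replaces nitrofurantoin),
and high-resistance (40% for every antibiotic). Because prevalences are
identical and drug identity does not affect the clinical course, the base
and low-trimethoprim scenarios produce identical inappropriate days and
QALY gains, differing only through drug costs — a relationship the
acceptance suite asserts.

## Sensitivity analyses

`run_psa()` draws joint parameter sets, runs the full paired scenario per
draw, and records (ΔCost, ΔQALY, NMB). Per-draw seeds derive from the
root seed and draw index through a fixed counter scheme, so single draws
are reproducible in isolation. `ceac()` turns the draws into the
acceptability curve P(λ·Δq − Δc > 0); its λ = 0 and λ → ∞ limits (shares
of cost-saving and QALY-gaining draws) are tested by enumeration.
`tornado()` re-evaluates the scenario at each parameter's range endpoints
(distribution bounds, or central 95% intervals for gammas), plus two
structural levers: the rapid test's turnaround (1 h to the culture
turnaround — at equality the arms coincide and NMB is exactly zero) and a
multiplicative scale on all resistance prevalences, the lever through
which the "impact of resistance" assumptions are stress-tested.

## Numerical choices

* Cycle length 1 h; horizon 10 000 h; no half-cycle correction (at
  one-hour cycles its effect is far below other uncertainties).
* Mass conservation tolerance 1e-9 relative, checked every cycle;
  violations abort.
* Transition-matrix rows sum to 1 by construction; verified to 1e-12.
* Equal turnarounds are permitted (the equal-arms null model used in
  testing); a rapid test *slower* than culture is rejected.
* `POST_FALSE_RESISTANT` retains the appropriate-treatment exit profile
  (the infection is still effectively treated) but pays second-line drug
  costs; its clinical consequence is not otherwise penalised.
* The BSI hazard is uniform across UTI states: inappropriate treatment
  raises BSI risk only through longer exposure, not a higher rate.
* Patients in the BSI state are costed at the BSI ICU blend and the BSI
  treatment drug price.
* Zero-count strata report per-patient NMB as `NA` (undefined), never
  zero.

## Test design and problem sizes

The suite validates the engine against an independent patient-level
Monte-Carlo microsimulation written from scratch in the test helpers
(50 000 simulated patients, coarse fast-absorbing hazards, a 600-hour
horizon), requiring agreement within 3 Monte-Carlo standard errors per
state — this exercises both arrival modes end to end. Property tests use
cohorts of 300–1000 and the analytic route for paired evaluations; PSA
reproducibility and stability checks use 10–80 draws, while the shipped
analysis default is 1000. These sizes were chosen so the whole suite
exercises every pathway at comfortable statistical power while remaining
quick to run routinely.

## Known limitations

* No transmission dynamics: stewardship externalities are excluded.
* Constant hazards (no time-varying discharge or mortality risk, no
  dependence on time already spent in state) — the standard Markov
  limitation.
* Placeholder values stand in for restricted-source inputs and are
  flagged in the configuration; headline magnitudes (though not the
  structural orderings) depend on them.
* QALY loss at death uses age only (not sex) at the band midpoint.
* Primary care, capital/implementation costs, and threshold pricing of
  the rapid test are out of scope.
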