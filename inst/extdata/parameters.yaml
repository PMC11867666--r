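# Default model parameters: point estimates with uncertainty distributions.
# Costs in 2022 GBP (inflation applied upstream of this file). Parameters
# whose published source is restricted or supplementary-only carry synthetic
# placeholder values chosen from the general literature; these are flagged
# "synthetic placeholder" in their source field and should be replaced when
# cohort-specific estimates become available.

bsi_hourly_rate:
  value: 3.1094709e-06
  distribution: {kind: gamma, shape: 0.3895395, scale: 34470.07}
  units: per hour
  source: "1253 bloodstream infections among 280462 UTI admissions over a 60-day window; -log(1 - 1253/280462)/(60*24)"

test_sensitivity:
  value: 0.95
  distribution: {kind: uniform, min: 0.75, max: 1.00}
  units: proportion
  source: "Sensitivity of culture and of the rapid impedance test to the empirical antibiotic (assumed, shared by both arms)"

test_specificity:
  value: 0.85
  distribution: {kind: uniform, min: 0.75, max: 1.00}
  units: proportion
  source: "Specificity of culture and of the rapid impedance test to the empirical antibiotic (assumed, shared by both arms)"

cost_standard_test:
  value: 15.67
  distribution: {kind: uniform, min: 11.7525, max: 19.5875}
  units: GBP per test
  source: "Urine test 4.98 + culture staff and consumables 10.69; one-off cost at point of use"

cost_bict_test:
  value: 15.67
  distribution: {kind: uniform, min: 11.7525, max: 19.5875}
  units: GBP per test
  source: "Set equal to the standard test: the technology price is unknown and threshold pricing is out of scope"

cost_bed_hour_general:
  value: 24.6
  distribution: {kind: uniform, min: 18.42, max: 30.78}
  units: GBP per hour
  source: "General ward cost per bed day, inflated and converted to per hour"

cost_bed_hour_icu:
  value: 85.07
  distribution: {kind: uniform, min: 63.8, max: 106.34}
  units: GBP per hour
  source: "ICU cost per day 1621.16, inflated and converted to per hour"

prop_icu_complicated:
  value: 0.139
  distribution: {kind: uniform, min: 0.10425, max: 0.17375}
  units: proportion
  source: "Proportion of complicated-UTI patients cared for in ICU"

prop_icu_uncomplicated:
  value: 0.0
  distribution: {kind: uniform, min: 0.0, max: 0.139}
  units: proportion
  source: "Assumed zero in the base case"

prop_icu_bsi:
  value: 0.0795
  distribution: {kind: uniform, min: 0.059625, max: 0.099375}
  units: proportion
  source: "Average ICU care within 24 h for BSI survivors and non-survivors"

turnaround_culture_h:
  value: 48
  units: hours
  source: "Urine culture susceptibility result, average of the 24-72 h reporting window"

turnaround_bict_h:
  value: 5
  units: hours
  source: "Bacterial impedance cytometry susceptibility result"

inappropriate_rx_proportion:
  value: 0.275
  distribution: {kind: uniform, min: 0.20, max: 0.35}
  units: proportion
  source: "Share of prescribing that is inappropriate, applied to the resistant population; literature range 20-35%, midpoint used"

mean_los_uti_days:
  value: 5.0
  distribution: {kind: uniform, min: 3.75, max: 6.25}
  units: days
  source: "Mean length of stay, susceptible/appropriately treated UTI; synthetic placeholder"

los_ratio_resistant:
  value: 1.3
  distribution: {kind: uniform, min: 1.0, max: 1.625}
  units: ratio
  source: "Multiplier on mean LoS for resistant infection on inappropriate empirical therapy; synthetic placeholder, lower bound 1 preserves the longer-stay assumption"

mean_los_bsi_days:
  value: 12.0
  distribution: {kind: uniform, min: 9.0, max: 15.0}
  units: days
  source: "Mean length of stay, bloodstream infection; synthetic placeholder"

mortality_fraction_uti:
  value: 0.028
  distribution: {kind: uniform, min: 0.021, max: 0.035}
  units: proportion of exits
  source: "Share of UTI hospital exits that are deaths, susceptible/appropriately treated; synthetic placeholder"

mortality_ratio_resistant:
  value: 2.0
  distribution: {kind: uniform, min: 1.0, max: 2.5}
  units: ratio
  source: "Multiplier on the death fraction for resistant infection on inappropriate therapy; synthetic placeholder consistent with roughly doubled mortality under inappropriate empirical treatment"

mortality_fraction_bsi:
  value: 0.15
  distribution: {kind: uniform, min: 0.1125, max: 0.1875}
  units: proportion of exits
  source: "Share of BSI exits that are deaths; synthetic placeholder"

qaly_decrement_uti_hour:
  value: 3.31e-05
  distribution: {kind: uniform, min: 2.4825e-05, max: 4.1375e-05}
  units: QALY per hour
  source: "Symptomatic UTI disutility 0.29 spread over 8760 h; synthetic placeholder"

qaly_decrement_bsi_hour:
  value: 6.28e-05
  distribution: {kind: uniform, min: 4.71e-05, max: 7.85e-05}
  units: QALY per hour
  source: "BSI disutility 0.55 spread over 8760 h; synthetic placeholder"

utility_norm:
  value: 0.8
  distribution: {kind: uniform, min: 0.6, max: 1.0}
  units: utility
  source: "Baseline utility applied to remaining life years lost at death; population-norm placeholder"

discount_rate_annual:
  value: 0.035
  units: per year
  source: "Discount rate applied to QALYs lost over the lifetime horizon; within-admission costs and effects fall inside one year and are undiscounted"

wtp:
  value: 20000
  units: GBP per QALY
  source: "Willingness-to-pay threshold"

horizon_h:
  value: 10000
  units: hours
  source: "Simulation horizon; long enough for the whole cohort to reach an absorbing state"

total_cohort:
  value: 280462
  units: patients
  source: "Adult inpatients with clinical suspicion of UTI, England, April 2017 - March 2019"

age_midpoint_years:
  value: {age_16_64: 40.0, age_65_100: 82.5}
  units: years
  source: "Midpoints of the two admission age bands, used for QALY loss at death"

life_expectancy_years:
  value: {age_16_64: 43.5, age_65_100: 7.6}
  units: years
  source: "Remaining life expectancy at the age-band midpoints; national life-table placeholder, age only (not sex-specific)"

age_sex_weights:
  value: {F.16-64: 0.17, M.16-64: 0.0612989, F.65-100: 0.47, M.65-100: 0.2987011}
  units: proportion of cohort
  source: "Admission weights by sex and age band; synthetic placeholder skewed to older women, with 16-64 males at 17192/280462"

antibiotic_cost_day:
  value:
    nitrofurantoin: 1.60
    trimethoprim: 0.60
    pivmecillinam: 9.50
    cefalexin: 1.20
    coamoxiclav_oral: 1.50
    gentamicin_iv: 4.00
    coamoxiclav_iv: 12.00
    bsi_treatment: 15.00
  units: GBP per day
  source: "Daily drug acquisition costs, mean price per unit where several are listed; formulary-derived placeholders"
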