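# Demonstration pipeline configuration.
#
# Runs the full analysis on synthetic claims for eight states.  State
# populations are approximate recent census totals; bed counts are
# plausible per-state inventories (ICU ~10% of total beds).  All sizes are
# deliberately small so the demo runs in seconds.

seed: 0

synthesis:
  n_enrollees: 2000
  date_range: ["2015-01-01", "2016-12-31"]
  admissions_per_enrollee: 0.6
  elective_share: 0.3
  nonelective_surgical_share: 0.2
  outpatient_surgeries_per_enrollee: 0.4
  outpatient_nonsurgical_per_enrollee: 0.3
  icu_fraction: 0.1
  complication_prob: 0.08

states:
  NY: {population: 19500000, hospital_beds: 42000, icu_beds: 4200}
  CA: {population: 39500000, hospital_beds: 74000, icu_beds: 7400}
  TX: {population: 28700000, hospital_beds: 60000, icu_beds: 6000}
  FL: {population: 21300000, hospital_beds: 55000, icu_beds: 5500}
  PA: {population: 12800000, hospital_beds: 37000, icu_beds: 3700}
  OH: {population: 11700000, hospital_beds: 33000, icu_beds: 3300}
  IL: {population: 12700000, hospital_beds: 32000, icu_beds: 3200}
  UT: {population: 3200000, hospital_beds: 5500, icu_beds: 550}

classifier:
  window_days: 30

utilization:
  share_level: state

revenue:
  denominator: inpatient_plus_outpatient_surgical
  complication_mdc: parent
  groups:
    musculoskeletal_circulatory_digestive: ["08", "05", "06"]

demand:
  prevalence: 0.05
  los_inpatient: 11
  los_icu: 9
  duration_days: 100
  scenarios:
    current_projection: {peak_day: 45, sd_days: 12, scale: 1.0}
    mandates_easing:    {peak_day: 40, sd_days: 10, scale: 1.5}
    universal_masks:    {peak_day: 60, sd_days: 18, scale: 0.4}
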