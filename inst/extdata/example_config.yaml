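# Example pipeline configuration (all prices synthetic).
# Time unit is years internally; ttd entries below are months and are
# converted on load (ttd_unit).
seed: 1
time_unit: years
currency_year: "2023/24"
cohort:
  start_age: 60
  prop_female: 0.40
engine:
  cycle_length: 0.01923076923   # 1/52 year
  horizon: 40
  discount_qaly: 0.035
  discount_cost: 0.035
fit:
  criterion: aic
  preferred_shape: increasing
utilities:
  pf: 0.77
  pd: 0.68
  age_decrement_per_year: 0.003
  ae_disutility: {intervention: 0.015, comparator: 0.010}
costs:
  state_pf_monthly: 133
  state_pd_monthly: 273
  terminal: 6265
  admin_monthly: {intervention: 1527, comparator: 819}
  ae_cost: {intervention: 450, comparator: 300}
  vial_sharing: false
  price_statistic: mean
  tender_prices:
    - {price: 210, share: 0.6}
    - {price: 185, share: 0.4}
ttd:
  intervention: 5
  comparator: 4
ttd_unit: months
thresholds: [20000, 30000]
scenarios: [base, median_price, vial_sharing]
psa:
  n_draws: 500
  se_frac: 0.10
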