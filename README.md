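# partsurv

Partitioned-survival cost-effectiveness modelling from digitised
Kaplan–Meier evidence, for pragmatic oncology health-technology appraisals
(HTA) — the setting where a health system must appraise an off-patent
biologic or biosimilar quickly, without a company submission, working only
from published survival figures and list/tender prices.

`partsurv` is aimed at HTA analysts and health economists. It covers the
whole chain:

1. **Evidence ingestion** — pseudo-individual patient data (pseudo-IPD) are
   reconstructed from digitised Kaplan–Meier curves and their
   numbers-at-risk tables via the Guyot interval algorithm
   (`reconstruct_ipd()`), with Kaplan–Meier estimation
   (`km_estimate()`) and empirical hazard diagnostics
   (`piecewise_hazard()`, `smoothed_hazard()`).
2. **Extrapolation** — censored maximum-likelihood fits of seven parametric
   families (exponential, Weibull, Gompertz, log-normal, log-logistic,
   gamma, generalised gamma) with AIC/BIC ranking, hazard-shape
   classification, and a joint selection policy that uses the same family
   in every arm (`fit_parametric()`, `fit_all()`, `select_families()`).
3. **The cohort model** — a three-state partitioned survival model
   (progression-free / progressed / dead). At each cycle boundary *t*:

   - dead(t) = 1 − S_OS(t)
   - progression-free(t) = min(S_PFS(t), S_OS(t))
   - progressed(t) = S_OS(t) − progression-free(t)

   with treatment exposure from a time-on-treatment curve or a fixed mean
   duration, trapezoidal half-cycle correction, and discounting at cycle
   midpoints (`partsa_spec()`, `build_traces()`, `accumulate_qalys()`,
   `accumulate_costs()`).
4. **Costing** — vial-count drug acquisition from body-metric
   distributions and relative dose intensity, with cost-minimal whole-vial
   combinations (or per-mg pricing under vial sharing) and market-share
   weighted tender prices (`expected_vial_cost()`, `weighted_price()`).
5. **Economics** — ICER = ΔC/ΔQ, iNMB(λ) = λ·w·ΔQ − ΔC, the QALY-shortfall
   severity modifier (weights 1.0/1.2/1.7) with a subsequent-treatment
   QALY correction, deterministic scenario analyses, and probabilistic
   sensitivity analysis with CEACs (`icer()`, `qaly_shortfall()`,
   `run_scenarios()`, `run_psa()`).

A synthetic trial generator (`make_reference_scenario()`,
`simulate_linked_endpoints()`, `digitize()`) emulates two-arm trials with
per-subject-coupled OS/PFS and the figure-digitisation process, so every
stage runs and is tested without access to confidential trial data or
tender prices.

## Worked example

```r
library(partsurv)

ref <- make_reference_scenario(seed = 1)   # synthetic two-arm trial + config
run <- run_pipeline(ref$config, ref$datasets, run_dir = NULL)
report_run(run)
```

```
Run 3c9783c (seed 1)

  Incremental LYG (undiscounted): 0.382
  Incremental QALYs (discounted): 0.264
  Severity-modifier weight:       x1.0
  Incremental cost (GBP):         11747.15
  ICER (GBP/QALY):                44576
  iNMB at_20000: -6476.48
  iNMB at_30000: -3841.15

  Scenarios: 5 run
```

The intervention arm (a biologic added to the chemotherapy backbone, OS
hazard ratio 0.75 and PFS hazard ratio 0.61 by construction) gains 0.38
undiscounted life-years and 0.26 discounted QALYs at an extra discounted
cost of £11,747, giving an ICER of £44,576/QALY; the negative iNMB values
say the gain is not worth the cost at thresholds of £20,000–£30,000/QALY
under these synthetic prices. The severity-modifier weight stays at 1.0
because the comparator arm's QALY shortfall (after adding the configured
subsequent-treatment QALYs) falls below both the proportional (0.85) and
absolute (12 QALY) thresholds.

```r
print(as.data.frame(run$scenarios), digits = 4)
#>           scenario   d_ly d_qalys d_cost  icer icer_tag
#> 1             base 0.3821  0.2635  11747 44576
#> 2 alt_distribution 0.8594  0.4656  12657 27186
#> 3     hazard_ratio 0.4661  0.3138  11871 37830
#> 4     median_price 0.3821  0.2635  11683 44331
#> 5     vial_sharing 0.3821  0.2635  10705 40622
```

The scenario rows swap in the designated sensitivity distributions, build
the intervention curves from the comparator fits times the configured
hazard ratios, switch to the weighted-median tender price, and allow vial
sharing. `report_run(run, redacted = TRUE)` suppresses every monetary
figure, mirroring the confidentiality handling under which only
incremental QALYs and life-years can be made public.

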