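---
title: "Methods: partitioned-survival cost-effectiveness modelling in partsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival cost-effectiveness modelling in partsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partsurv)
```

`partsurv` implements a pragmatic appraisal pipeline for oncology
treatments whose evidence arrives as published survival figures rather
than patient-level data. This vignette is the package's own account of the
science: the model, its assumptions, the tunable parameters, what the
synthetic data generator does and does not emulate, and the numerical
choices behind every default.

## The partitioned survival model

Three health states — progression-free (PF), progressed disease (PD),
dead — are occupied directly from the overall-survival and
progression-free-survival curves, with no transition-probability matrix:

* dead$(t) = 1 - S_{OS}(t)$,
* PF$(t) = \min\{S_{PFS}(t), S_{OS}(t)\}$,
* PD$(t) = S_{OS}(t) - \mathrm{PF}(t)$.

The `min` clip handles digitised curves, which can cross; clipped cycle
boundaries are counted and reported rather than raised as errors
(`attr(trace, "n_clipped")`). Occupancies sum to one by construction and
the dead state is monotone whenever $S_{OS}$ is a valid survival function.

Two structural assumptions are inherited from the appraisal setting:
subsequent treatment lines are assumed cost-effective, and no interaction
is assumed between the appraised line and the efficacy or duration of
later lines. Their operational consequence is that *all* costs and QALYs
of subsequent treatments are excluded from the incremental results — the
model compares the appraised line only. The excluded survival benefit of
later lines re-enters in exactly one place: the severity-modifier
computation (below).

### Treatment exposure

Time on treatment either follows a discontinuation (TTD) curve, capped at
the PF occupancy, or a fixed mean duration $d$: exposure equals PF
occupancy for $t < d$ and zero after. The capped-fixed-duration rule is
one defensible reading of how a mean duration interacts with early deaths
— it preserves the intended exposure horizon while never treating more
people than are alive and progression-free. The alternative (scaling
exposure so the *mean* equals $d$ exactly despite deaths) would charge
treatment to dead patients' cycles; we rejected it.

### Cycles, discounting and the accumulation rule

* cycle length: default 1/52 year (one week); horizon: default 40 years
  (a 60-year-old cohort reaches age 100). The sources this design follows
  do not state their cycle structure; a weekly cycle makes half-cycle
  effects negligible, which we verify against continuous-time oracles.
* Accumulation is trapezoidal over cycle boundaries (the half-cycle
  correction), and each cycle's increment is discounted at its midpoint
  with the discrete factor $(1+r)^{-t}$, $r = 3.5\%$/year for both costs
  and QALYs by default (the rate is the standard appraisal-manual value,
  configurable).
* With these defaults, discounted life-years agree with the adaptive
  quadrature oracle $\int_0^T (1+r)^{-t} S(t)\,dt$ to well within 0.5%,
  and halving the cycle length moves results by under 0.2% (both are
  tested).

### Utilities

State utilities (defaults 0.77 PF / 0.68 PD, the published first-line
values; 0.73/0.64 are the corresponding second-line inputs) are
multiplied by an age index $\max\{1 - \delta\,(a - a_0),\,0\}$ normalised
to 1 at the cohort's start age $a_0$; the decrement-per-year $\delta$ is a
configuration input because the published age-decrement regression is an
external source, not something this package should hard-code. One-off
adverse-event disutilities (already weighted by per-arm event
probabilities) are charged at model entry, as are adverse-event costs.

## Survival evidence

### Pseudo-IPD reconstruction

`reconstruct_ipd()` implements the Guyot interval algorithm: within each
numbers-at-risk interval, censorings are assumed evenly spread and their
count is adjusted iteratively until the implied number at risk matches the
next risk-table entry, while event counts at each digitised drop follow
the running product-limit identity. When a total event count is available
the final interval is calibrated to it; when it is not, that step is
skipped and the tail censoring rate is extrapolated from the earlier
intervals (both code paths exist because publications are inconsistent
about reporting totals).

Two conventions are deliberate and self-consistent with the package's own
`digitize()`:

* **Risk-table timing.** A number at risk reported at time $t>0$ counts
  subjects under observation *strictly beyond* $t$ — i.e. after any events
  plotted at $t$. Intervals are therefore $(t_i, t_{i+1}]$. Published
  tables more often use the "just before $t$" convention; for a pipeline
  that both simulates digitisation and reconstructs from it, what matters
  is that the two ends agree, and the chosen convention makes the clean
  single-drop example reconstruct exactly.
* **Censoring placement.** Within an interval, censorings sit at evenly
  spaced times. This perturbs person-time slightly (it cannot be known
  from a figure) but leaves the KM step heights untouched.

Non-monotone digitised coordinates (extraction noise) are repaired by a
running minimum before reconstruction, since a survival function must be
non-increasing. Requested censorings can never exceed the people actually
at risk, and a risk table that demands more people at risk than the drops
permit raises an error naming the offending interval.

Reconstruction fidelity is tested two ways, which answer different
questions: against the *digitised curve* (the algorithm's input) the KM of
the reconstruction agrees to sup-norm ≤ 0.02 even at a coarse 60-point
grid; against the *original data's* KM, agreement to 0.02 requires a fine
digitisation grid (250 points in the tests), because at a 60-point grid
the snapping of drop times to half a grid cell (~0.026 year) already
moves a steep KM by more than 0.02 regardless of any reconstruction.

### Parametric fitting and selection

Seven families are fitted by censored maximum likelihood through
`flexsurv` — the practitioner's tool for HTA survival work — using the
stable log-time (Prentice) generalised-gamma parameterisation
$(\mu, \sigma, Q)$, which nests Weibull ($Q=1$), log-normal ($Q=0$) and
gamma ($Q=\sigma$); positive parameters are estimated on the log scale
and the reported covariance lives on that estimation scale (it is what
the PSA samples from). AIC and BIC are recomputed from the log-likelihood
so the identities hold exactly. The Gompertz shape may be negative
(improper survival with a plateau); the finite model horizon truncates
the plateau mass.

Hazard shapes (`classify_hazard_shape()`) come from the analytic hazard
on a dense grid, with tolerance-guarded sign counting; classification
stops where survival falls below $10^{-10}$, because density and hazard
evaluations beyond that point are underflow noise.

The selection policy codifies the narrative rule used in appraisals: the
base-case family is the best summed information criterion among families
whose hazard-shape tag matches the clinically asserted shape (default
"increasing", configurable, disabled with `NULL`) *in every arm* — the
same family is always used across arms, with ties broken by summed AIC.
The sensitivity family is the converged family whose extrapolated
survival at the horizon differs most from the base case, summed over
arms. On synthetic data this policy can be exercised but not validated
against any particular appraisal's expert choice, which is the honest
limit of what a reusable implementation can do.

### Hazard diagnostics

`piecewise_hazard()` is the definitional estimator (events over
person-time per bin; default bin 3 months). `smoothed_hazard()` is a
spline-smoothed hazard: Poisson regression of event counts on a cubic
B-spline basis over fine time bins with a log person-time offset, interior
knots at event-time quantiles (default 3). Fitting on the log-hazard scale
makes the estimate positive by construction; its integral tracks the
Nelson–Aalen total within 15% on large samples (tested).

## Costing

Drug acquisition is vial-based: per administration, required mg = dose ×
body metric × relative dose intensity. Without vial sharing the cost is
the *cost-minimal* whole-vial combination covering the dose (dynamic
programming on 1 mg units, verified against brute-force enumeration);
cost-minimisation, not waste-minimisation, is the payer's objective, and
the two differ when price per mg varies across vial sizes. With sharing,
cost is mg × the cheapest price per mg. The body-metric expectation uses a
deterministic 199-point quantile grid per sex (log-normal or empirical
inputs) so the deterministic base case is exactly reproducible — no Monte
Carlo enters the deterministic pipeline.

Tender prices enter as a market-share-weighted mean (base case) or
weighted median (sensitivity analysis), the median being the smallest
price whose cumulative share reaches 0.5. All prices shipped with the
package are synthetic: the real tender prices are confidential and the
pipeline is designed never to need them.

Administration/monitoring costs are monthly per-regimen inputs prorated
per cycle (a 1-week cycle carries 12/52 of a monthly cost); state costs
(defaults £133/month PF, £273/month PD) accrue on occupancy; the terminal
cost (default £6,265) is charged on each cycle's new deaths at that
cycle's discount factor.

## Severity modifier

The severity weight multiplies QALY gains in the iNMB. It is derived from
the QALY shortfall of standard care against the age/sex-matched general
population: absolute shortfall $= Q_{gen} - Q_{SoC}^{adj}$, proportional
$= 1 - Q_{SoC}^{adj}/Q_{gen}$. $Q_{gen}$ is a life-table product-sum with
a half-year convention (deaths mid-year, utilities and discounting at
mid-year). Because the model excludes subsequent treatment lines,
$Q_{SoC}$ alone would understate standard-care QALYs and inflate the
modifier; a configured subsequent-treatment QALY addition is therefore
added *before* the shortfall is computed — and only there, never to the
ICER's increments. This correction double-counts the progressed-state
QALYs of the appraised line and assumes every PFS event is a progression,
both of which *overstate* standard-care QALYs; the bias is conservative
(against triggering a higher weight near a threshold) and is the accepted
trade-off of the pragmatic approach.

The weight thresholds default to the current appraisal-manual scheme
(proportional ≥ 0.85 or absolute ≥ 12 → ×1.2; ≥ 0.95 or ≥ 18 → ×1.7) but
are configuration, not constants, since schemes change.

## Probabilistic sensitivity analysis

Survival parameters are drawn multivariate normal on the estimation scale
from each fit's covariance (so positivity constraints are respected after
back-transformation); utilities are beta and costs gamma, by method of
moments. Dispersion inputs default to a standard error of 10% of the mean
— a conventional choice in the absence of published dispersions, and
deliberately a configuration default, not a claim. The tender price is
held fixed by default (`psa$sample_price`) because price is a negotiated
quantity, not a sampling uncertainty; TTD fixed durations are likewise
fixed. Setting `vcov_scale = 0` and `se_frac = 0` makes every draw equal
the deterministic result exactly, which is the degeneracy test. A
non-positive-definite covariance is repaired to the nearest positive
semi-definite matrix with a warning.

## The synthetic reference scenario

`make_reference_scenario()` defines the study conditions under which the
pipeline is exercised:

* Two arms of 500 subjects, 3 years' follow-up, 3%/year dropout. The
  comparator OS is Weibull(shape 1.2, scale 2.2 years; median ≈ 1.6
  years) and PFS Weibull(1.1, 0.85; median ≈ 7 months) — plausible for
  first-line metastatic colorectal cancer. Intervention curves apply OS
  HR 0.75 and PFS HR 0.61 (the published second-line meta-analytic
  values, used here as a realistic effect size), in closed form so the
  truth stays Weibull.
* OS and PFS are coupled per subject by a shared uniform draw (comonotone
  coupling): the simplest mechanism that guarantees PFS ≤ OS per subject
  whenever the marginals are ordered, which is validated numerically on a
  grid before simulation.
* `digitize()` emulates figure extraction: KM drop locations snap to the
  nearest point of a regular grid (as when clicking step corners at
  finite figure resolution), numbers at risk are tabulated at a fixed
  interval, and optional uniform jitter (default off) models extraction
  error. Jitter is off by default so round-trip tests run at exact
  tolerances; real digitisation error is unknown and would be additional.
* Cohort age 60, 40% female; utilities 0.77/0.68; state costs £133/£273
  per month; terminal cost £6,265; fixed mean treatment durations 5 and 4
  months (intervention/comparator); administration/monitoring £1,527 and
  £819 per month — the published non-confidential inputs. Tender prices
  (eight synthetic quotes around £200 per 100 mg with synthetic shares),
  the body-weight/BSA log-normals, the synthetic life table
  (`make_synthetic_life_table()`, a Gompertz-style schedule), the general
  population utility norm (0.80 at 60, −0.004/year) and the
  subsequent-treatment QALY addition (0.8 QALYs) are stand-ins chosen
  once at realistic magnitudes; they are inputs the real appraisal would
  take from confidential or external sources.

What the generator does *not* emulate: real digitisation noise,
informative censoring, non-proportional hazards between arms, cure
fractions, and any specific published trial's curves. Passing tests
therefore demonstrate the pipeline's internal correctness and calibration
under known truth — not agreement with any appraisal's clinical inputs.

## Test problem sizes

The suite exercises the generator at the sizes that make each check
informative: n = 10,000 for Monte-Carlo means and KM consistency
(sup-norm < 0.02), n = 300 with a 60-point digitisation grid for the
reconstruction round trip, n = 1,000 per family for parameter recovery
(true parameters chosen so each parameter's asymptotic relative standard
error sits well under the 10% tolerance — identifiability, not
convenience), 50 replicates for the model-selection frequency check, and
1,000 PSA draws for the near-linearity check (probabilistic mean ΔQALY
within 10% of deterministic). The full pipeline runs in well under a
minute on one core.

## Known limitations

* The partitioned structure cannot represent treatment sequences; its
  increments are only as meaningful as the two structural assumptions
  above.
* Extrapolation dominates incremental life-years: the scenario swapping
  in the sensitivity families routinely doubles ΔLY in the synthetic
  scenario. This is a faithful property of the method, not an artifact —
  it is why appraisal practice insists on hazard-plot diagnostics and
  clinical plausibility alongside information criteria.
* The severity-modifier QALY addition is a single scalar input; the
  underlying later-line model is out of scope.
* Vial costing assumes a single vial menu per drug and no dose
  banding/capping policies.
* The general-population calculation uses a pre-mixed life table; it does
  not model sex-specific mortality separately.
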