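---
title: "Externally controlled comparisons over repeated lines of therapy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Externally controlled comparisons over repeated lines of therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extarm)
```

## The estimation problem

A single-arm trial cohort is to be compared with an external control built
from retrospective chart review. The control is observed as *lines of
therapy* (LOTs): a patient re-enters the analysis at the start of every line
for which the eligibility criteria hold, so the analysis unit is the LOT,
one patient can contribute several units, and the units of one patient are
correlated. Three design features follow, and the whole package is organized
around them:

1. **Eligibility is assessed per line.** Each control LOT is judged
   independently against the testable criteria (ECOG 0–1, prior platinum
   therapy, EGFR Exon20ins testing before the line started), except that a
   line containing the trial drug and every later line of that patient are
   removed together — once the trial treatment has been received, later
   outcomes are contaminated. Criteria that the source data cannot express
   (laboratory values, washout windows) are out of scope by design;
   `assemble_cohort()` reports a per-rule exclusion count with a fixed rule
   order so the attribution of exclusions is reproducible. Whether a
   patient's later lines remain eligible after an intermediate line failed a
   criterion is not specified by the design; here each line is judged on its
   own (only the trial-drug rule looks across lines), and this choice is
   deliberate: an ECOG violation at line 2 says nothing about eligibility at
   line 3, whereas receiving the trial drug does.

2. **The estimand is the ATT.** The trial cohort is the target population;
   controls are reweighted to match it. The propensity score is modelled as
   the probability of *trial* membership given the baseline covariates,
   *e*(*x*) = *P*(TRIAL | *x*), by main-effects logistic regression, and each
   control LOT receives the odds weight *e*(*x*)/(1 − *e*(*x*)); trial units
   keep weight 1. This is the standard ATT odds weight: with it, the
   weighted control covariate distribution converges to the trial's under a
   correctly specified model (a property the test suite checks on large
   simulated cohorts). Weights are then rescaled by a common factor so the
   control weights sum to the number of control LOTs; this keeps the
   nominal sample size and changes no relative weight. No trimming is
   applied by default — the weight distribution is part of the diagnostics —
   and the propensity fit refuses to proceed under perfect separation
   rather than returning near-degenerate weights.

3. **Variance must respect the patient.** All adjusted analyses use a
   cluster-robust sandwich variance with patients as clusters: score
   contributions are aggregated within `patient_id` before the outer
   product, so repeated lines of one patient do not masquerade as
   independent information. The GLM sandwich is CR0 (no small-sample
   factor; `cr = "CR1"` adds the usual m/(m−1)·(n−1)/(n−k) factor); the Cox
   sandwich is the grouped infinitesimal-jackknife estimator of
   `survival::coxph`. The one exception is the *unadjusted* 2×2 response
   analysis, which uses the classical Wald variance of the four cell
   counts — the convention for reporting a raw contingency-table contrast.

## Endpoints and their conventions

Best response is a per-LOT binary (at least a partial response); LOTs with
no recorded response are excluded from response-rate analyses only and kept
for time-to-event endpoints. The response contrast is reported both as an
odds ratio (weighted logistic model) and as a response rate ratio from a
log-link binomial model; when the log-binomial likelihood fails to
converge — a routine occurrence with log links — the rate ratio falls back
to a robust-variance Poisson fit and the result is flagged in the `note`
column.

PFS, TTNT and OS are stored as integer days from the line's index date with
event indicators; months are reported as days/30.4375 throughout, a fixed
divisor chosen so conversions are reproducible (reported medians can differ
in the second decimal under other conventions). Kaplan–Meier estimation
uses weighted event and at-risk sums with weighted Greenwood variance and
pointwise log(−log) confidence limits. The median is the first time the
survival estimate falls to one half or below; its confidence limits are the
first times each pointwise survival limit falls to one half (the
Brookmeyer–Crowley construction). A curve that never reaches one half
yields a flagged undefined median (`NR` in rendered tables), not an error.
Cox models use Efron tie handling — day-resolution real-world data tie
often — with a Newton tolerance of 1e-9.

Two-sided p-values come from the normal approximation on the log scale, and
95% intervals are exp(log-estimate ± 1.96·SE) with the method's SE.

## The neighbour-rule imputation

Metastatic-site fields in chart-review data are either abstracted as a
block or absent as a block, so missingness is block-wise per LOT. The three
rules, applied per site within a missing block:

* both an earlier and a later observed line exist: impute the shared value
  when they agree; impute *presence* when they disagree, in either
  direction (absence→presence or presence→absence). Treating both
  directions as presence is conservative toward disease burden; the
  motivating data only exhibited the absence→presence case, so the
  presence→absence convention is a package decision, covered by a test.
* only an earlier line: last observation carried forward;
* only a later line: its value carried backward;
* no observed line: left missing and counted unimputable.

"Earlier/later" mean the *nearest observed* line by line number, so a chain
of missing lines still imputes from the closest observed line on each side
(the motivating data had no chained-missing case; this generalization is
covered by a dedicated test). Imputation never alters an observed value,
never increases missingness, and is idempotent — all tested properties.
`fixture_missingness_cohort()` reproduces the motivating pattern exactly
(9 block-missing LOTs from 8 patients: 3 both-neighbour including one
discordant case, 4 prior-only, 2 subsequent-only) and imputes completely.

## Balance diagnostics

For a binary covariate the SMD is (p_T − p_C) / sqrt((p_T(1−p_T) +
p_C(1−p_C))/2), with the weighted control proportion after ATT adjustment;
the direction is trial minus (weighted) control, a convention that must be
fixed because a signed SMD for multi-level covariates is not otherwise
well-defined. Multi-level covariates (prior lines, age category) report
per-level SMDs plus a non-negative Mahalanobis-type summary over the level
proportions. Degenerate levels (identical proportions of 0 or 1 in both
cohorts) give SMD 0; unequal degenerate proportions are flagged infinite
rather than silently dropped. The propensity-score ranges per cohort are
reported as an overlap diagnostic (`glance()` on the fit); overlap is a
thing to inspect, not an assertion the package enforces.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate two-cohort LOT tables with the
statistical structure the analysis assumes. Defaults define the package's
reference study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_trial` | 114 | trial patients, one LOT each |
| `n_control_patients` | 38 | control patients |
| `lot_rate` | 0.448 | mean of the Poisson extra-LOT count, truncated at 3; gives E[control LOTs] ≈ 55 |
| `covariate_margins` | study Table-1 marginals | per-cohort category probabilities |
| `frailty_variance` | 0.5 | variance θ of the mean-1 gamma frailty shared by a patient's outcomes |
| `hazard_models` | rates log 2/148 and log 2/349 per day; treatment log-HRs log 0.42, log 0.48 | exponential baselines for progression and death matched to control medians of 4.86 and 11.47 months |
| `response_model` | intercept logit(9/54), treatment log 2.8 | logistic best-response model |
| `censor_rate`, `admin_cap_days` | 1/700 per day, 1095 days | independent exponential censoring and administrative cutoff |
| `missing_block_prob` | 9/55 | MCAR block-masking probability on control LOTs |
| `response_missing_prob` | 1/55 | control LOTs with unevaluable response |
| `progression_prob` | 0.1 per line | chance an absent metastatic site appears at the next line |

Construction guarantees, not afterthoughts: PFS = min(progression, death)
and TTNT = min(progression + delay, death) with a shared per-LOT censoring
time, so PFS ≤ OS and TTNT ≤ OS hold by construction; metastatic sites are
monotone across a patient's lines and the prior-line count increments;
masking is applied only where an observed neighbouring line remains, so
every masked block is imputable (set `allow_unimputable = TRUE` to lift
this); equal seeds give byte-identical output and the caller's RNG state is
untouched.

One consequence of the composite construction deserves emphasis: a log
hazard ratio applied to the *progression* hazard alone does not produce a
proportional-hazards composite PFS, because the death component is not
scaled. Simulations that need an exact composite hazard ratio (the
parameter-recovery tests) scale the progression and death hazards
together. The frailty default θ = 0.5 is a free modelling choice — the
within-patient correlation of the motivating data is not reported
anywhere — and should be treated as a scenario parameter, not an estimate.
The TTNT delay (mean 45 days) and the per-line site-progression probability
are likewise scenario parameters.

What the generator deliberately does not emulate: informative censoring,
covariate evolution within a line, competing risks, site-level (non-block)
missingness, and any dependence of masking on outcomes (masking is MCAR).
Passing tests therefore show the pipeline is correct under these
assumptions; they cannot show robustness to, e.g., outcome-dependent
missingness in real chart-review data.

## Calibration evidence in the test suite

The suite ties each stage to an independent oracle or a closed form rather
than to itself: logistic and Cox coefficients are checked against
brute-force likelihood maximization on ≤ 8-record datasets; the weighted
Kaplan–Meier median against the closed-form exponential median at n = 5000;
the ATT-weighted Cox estimate against a known conditional hazard ratio of
0.42 on confounded cohorts with ≥ 1000 events per replicate; and the
published unadjusted 2×2 response row (odds ratio 2.92, rate ratio 2.21) is
reproduced from its printed counts to printed precision.

Variance calibration is assessed on null cohorts with frailty-correlated
repeated lines (150 trial patients, 60 control patients averaging ~2.5
lines, θ = 1, 1000 replicates): the patient-clustered Wald test of the
treatment term holds the nominal 5% level within [0.03, 0.07] while the
naive-variance test exceeds it, and the robust SE exceeds the naive SE in
essentially all replicates. A caveat worth recording: after ATT weighting
the CR0-type sandwich becomes mildly liberal at small control cluster
counts (propensity-estimation noise and weight variability are not
accounted for), a known small-sample property of plug-in sandwich
estimators; the calibration property above is therefore stated for the
clustered variance itself, and weighted small-sample inference should be
interpreted with that in mind.

Problem sizes used by the simulation-based tests (10 000 patients for
marginal fidelity, 2000–4000 per arm for recovery and balance properties,
50–1000 replicates for distributional properties) were chosen so that
Monte-Carlo error is small relative to each assertion's tolerance.

## Known limitations

* The propensity model is main-effects only; interactions or splines are
  out of scope, as are matching, stratification, entropy balancing and
  overlap weights.
* No proportional-hazards diagnostics are provided; the Cox hazard ratio is
  reported as a summary contrast regardless.
* The eligibility engine covers only schema-representable rules; date
  windows and lab-based criteria are not modelled.
* Multiple imputation is out of scope; the neighbour rules are single,
  deterministic imputations, and their audit (`ImputationAudit`) is the
  honesty mechanism.
* The renormalized weights are used in the sandwich as given (the point
  estimate is invariant to the rescaling; the variance is not); this
  matches the stated purpose of renormalization — reflecting the nominal
  sample size in the uncertainty.
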