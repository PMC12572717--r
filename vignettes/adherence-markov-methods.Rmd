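---
title: "Modeling long-term adherence trajectories with proportional-odds Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling long-term adherence trajectories with proportional-odds Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcmarkov)
```

## The problem

Oral anticoagulation in atrial fibrillation is lifelong therapy, and even
small lapses in adherence carry stroke risk. A single yearly proportion of
days covered (PDC) cannot distinguish a patient who takes 90% of doses
every month from one who is perfect for nine months and then stops.
`pdcmarkov` models adherence as a *trajectory*: the PDC of consecutive
90-day windows, binned into ten ordinal states, followed over five years
and predicted from the first year of dispensing data plus two baseline
covariates (age and the CHA2DS2-VASc stroke-risk score).

## From claims to windowed states

The PDC engine consumes raw dispensing rows (patient, dispense date, agent,
days supplied) and hospitalization intervals.

* **Carry-over.** An early refill is shifted forward to the end of the
  previous supply, so supply is conserved and no day is double counted.
  The shift-based interval engine is provably equivalent to a day-level
  simulation that stockpiles supply and consumes one unit per day; the
  test suite checks this equivalence exactly on 1,000 random histories.
* **Agent pooling.** All agents in the class are one supply stream, so
  switching (about 12% of patients in the synthetic cohort) retains
  carry-over credit.
* **Hospital credit.** In-hospital days count toward the numerator because
  hospitals supply medication. The engine defaults to a *union* rule — a
  hospital day that is already drug-covered is not counted twice — because
  a plain sum could push the numerator past the 90-day denominator before
  capping; the summing variant is available (`hospital_credit = "sum"`)
  since claims pipelines differ on this point.
* **Windows and binning.** `PDC = min(covered + hospital, 90)/90` per
  window; percentage bins are left-closed (`[0,10), ..., [80,90)`) with
  `[90,100]` closed on top. Since windowed PDC is always `days/90`, a
  small tolerance (1e-9) keeps integer day counts on the intended side of
  each bin edge despite floating-point division.
* **Index date and eligibility.** The index date defaults to the first
  dispense; a patient needs at least 2 fills and 60 total days supplied
  (a pragmatic reading of "at least two months of prescriptions"), both
  configurable.

## The transition model

For outcome windows \(t = 5,\dots,20\) the ordinal state \(Y_t\) follows a
first-order proportional-odds Markov model:

\[
P(Y_t \ge j \mid x_t) = \operatorname{logit}^{-1}(\alpha_j + x_t^\top\beta),
\qquad j = 2,\dots,10 .
\]

Higher linear predictor means better adherence, so positive coefficients
read as adherence-increasing. The design \(x_t\) contains:

* indicator coding of the previous state (reference: state 10, the modal
  state), which is the Markov conditioning;
* the window index, linear and centered. Time is kept linear because the
  candidate-model ladder only ever treats it as an interaction partner;
  a spline encoding is available (`time = "rcs4"`);
* restricted cubic splines with four knots for age, CHA2DS2-VASc score and
  the credited days of first-year windows 1–4. Knots default to the
  0.05/0.35/0.65/0.95 quantiles, the standard choice for four knots; for
  heavily tied variables (days covered mass at 90) the quantiles of the
  distinct values are used instead, with a warning. Fixed knots can be
  frozen in the `model_spec` for simulation work;
* products of the window-3 and window-4 spline columns with centered time
  in the final model, letting the predictive strength of late-first-year
  adherence change over the horizon.

Estimation is plain maximum likelihood: Newton–Raphson with the analytic
gradient and Hessian (implemented in C++), a Levenberg-style ridge and
backtracking line search, a BFGS fallback, and the intercept-only solution
(marginal cumulative log-odds) as the start. Ordered intercepts are
maintained by a finite likelihood barrier on non-positive category
probabilities rather than a hard reparameterization, which keeps the
covariance directly interpretable; in practice the barrier is never active
at the optimum. The covariance is the inverse observed information
(analytic Hessian at the optimum). No cluster-robust correction is applied:
the Markov conditioning is the modeled dependence mechanism. The fit is
deterministic; convergence requires the gradient sup-norm below
`tol * (1 + |loglik|)` and failures are flagged, not thrown.

Model comparison fits a ladder of ten candidate structures (the basic
model; adding time interactions on windows 3–4; only two windows; dropping
age, the score, or both; dropping each window in turn) on shared knots and
reports AIC and likelihood-ratio tests against the basic model; the
minimum-AIC member is flagged as final.

## State occupancy and summaries

Starting from the observed window-4 state — never a predicted one — the
one-step distribution at window 5 is propagated by recursive matrix
multiplication, \(\text{row}_t = \text{row}_{t-1} P_t\), where \(P_t\) is
the subject-specific transition matrix at window \(t\). This unconditions
on the unknown intermediate states and yields the state occupancy
probabilities (SOPs), a 16 × 10 matrix per patient. *Mean time in state*
is the column sum, in 90-day units; states can be collapsed to the
4-state (0–9 / 10–69 / 70–89 / 90–100%) or 3-state groupings for
sensitivity analyses. The horizon is windows 5–20 (years 2–5) by default;
`horizon = 21` adds the extra quarter some registries report.

Correctness of the recursion is established two ways in the tests: exact
agreement (1e-12) with brute-force enumeration of all \(10^3\) paths over a
short horizon, and agreement within Monte-Carlo error with 200,000
forward-simulated trajectories over the full horizon. Conservation
identities (rows sum to 1; mean times sum to the horizon; collapsing
commutes with summing; the recursion composes across any split point) are
asserted at tolerances 1e-10 to 1e-12.

## Diagnostics

* **Subject-level calibration.** Each subject's mean predicted expected
  state (probability-weighted state index, averaged over windows) versus
  the mean observed state, grouped into deciles (equal sizes, ties broken
  by subject id for determinism). A time-stratified variant splits the
  horizon into early (window 5), middle (6–12) and late (13–20) strata,
  and a GAM smoother (penalized spline, GCV) gives the continuous version.
  Calibration is computed in-sample, as is conventional for internal
  validation of this design.
* **Transition calibration.** One-step predicted probabilities of the
  states of clinical interest (90–100%, 80–89%, 0–9%) binned into deciles
  against observed event fractions.
* **Discrimination.** The SOP distribution width: per state and window,
  the IQR length (linear-interpolation quantile convention, stated because
  this is a headline statistic) of the SOP across subjects, time-averaged,
  with a subject-resampling bootstrap (100 repetitions by default) for the
  median and 2.5/97.5 percentile envelope. Wide distributions mean the
  model separates subjects for that state; on synthetic cohorts the
  extreme states (10 and 1) are far wider than the intermediate ones,
  which sit near zero — the same asymmetry the underlying study design
  exhibits.
* **Mean-time error.** Per subject, the absolute difference between the
  SOP-derived mean time in the top state and the observed count of
  windows in that state; summarized by median and IQR. "Observed time in
  state" is defined as the count over windows 5–20.

The core correctness argument for the whole stack is *self-calibration*:
data simulated from the fitted model itself must calibrate against it.
The acceptance tests check that the decile slope lies in (0.9, 1.1) and
every transition-calibration decile sits within 3 binomial standard errors
of the diagonal.

## The synthetic cohort generator

Registry claims cannot be shipped, so the generator is a first-class,
tested module that emulates the study population the methods target:

* ages from a two-sided half-normal around a median of 78 (lower sd 7.4,
  upper sd 10.4, truncated to 45–100), reproducing an IQR of roughly
  73–85; CHA2DS2-VASc scores 1–9 drawn from a distribution with mode 4–5
  and median 5;
* first-year adherence from a per-patient frailty model: each window's
  missed days are zero with probability 0.55/0.52/0.45/0.42 (windows 1–4)
  or exponential (means 9/14/18/22 days) scaled by a log-normal patient
  frailty (sdlog 0.5) — yielding median credited days 90 with lower
  quartiles in the mid-80s, declining slightly over the year. Caps on the
  first two windows keep every generated patient eligible;
* windows 5–20 simulated from a known proportional-odds transition model
  (`default_true_model()`) whose covariate effects are closed-form target
  shapes — age rising to a plateau near 75, a modest positive score
  effect (about log(1.091)/2 per point), window effects nearly flat above
  89 covered days with a steep drop below, stronger for windows 3–4 and
  attenuating with time — projected by least squares onto fixed-knot
  spline bases, so the truth is *exactly representable* by the fitted
  model class and parameter recovery can be asserted coefficient by
  coefficient. The reference distribution at the covariate centers puts
  0.95 on the top state; persistence coefficients make low states sticky;
  a mild negative time trend produces the characteristic pattern of a
  median state of 10 at every window with a lower quartile that widens
  from 9 to 1 across years 2–5;
* claims are then *reverse-engineered*: each window's credited days are
  placed as a coverage block, about 10% of patient-years get a 3–14 day
  hospital stay carved out of covered days (so stays never create or
  destroy credit), runs are chunked into 30-day fills with occasional
  early refills (exercising carry-over) and single agent switches
  (exercising pooling). The round trip claims → PDC engine → states
  reproduces the stored ground truth exactly, integer for integer.

All randomness flows from one seed through counter-based per-patient
substreams, so patient *i*'s data is invariant to the cohort size — useful
when scaling simulations up and down.

What the generator does **not** emulate: mortality and censoring (the
target population conditions on 5-year survival), insurer switching,
agent-specific adherence differences, dose changes, and seasonality.
Passing tests therefore demonstrate the correctness of the machinery and
the behavior of the method under its own assumptions, not performance on
real registries.

## Numerical choices and problem sizes

* Convergence: gradient sup-norm below `1e-8 * (1 + |loglik|)`; Newton
  steps with ridge fallback; probabilities clamped at 1e-12 only inside
  gradient/Hessian evaluation near the barrier.
* Quantiles everywhere use the linear-interpolation (type 7) convention.
* Decile ties broken by stable subject-id rank.
* Degenerate inputs: constant predictions yield a flat calibration
  smoother; single-subject width summaries are zero with a message;
  unseen previous-state levels in prediction snap to the nearest observed
  level with a message.
* Simulation studies in the test suite use cohorts of 800–3,000 patients
  (16 transitions each) and 100 replicates for parameter recovery and
  model selection, sizes at which the spline coefficients are estimated
  with standard errors small enough for coverage statements to be
  meaningful while the full suite stays fast.

## Known limitations

* The proportional-odds assumption is imposed, not tested; a
  partial-proportional-odds extension is out of scope.
* Variance estimates condition on the Markov specification being correct;
  a sandwich option would guard against residual within-patient
  dependence but is not implemented.
* In-sample calibration flatters any model; external validation requires
  data the package cannot ship.
* The intermediate adherence states are intrinsically hard to
  discriminate — their SOP widths are an order of magnitude below the
  extreme states' — so clinical use should focus on the top and bottom
  states, and on mean time in the top state.
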