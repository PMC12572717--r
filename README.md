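# pdcmarkov

Modeling and predicting long-term adherence to chronic oral therapy —
direct oral anticoagulants (DOACs) in atrial fibrillation in particular —
from pharmacy dispensing claims.

Medication adherence is usually summarized as a single proportion of days
covered (PDC), which hides the trajectory: a patient covered 95% of year 1
may still abandon therapy in year 3. `pdcmarkov` instead models the PDC of
consecutive 90-day windows as an ordinal state and predicts the whole
5-year trajectory from the first year of dispensing data.

## The model

1. **PDC engine.** Dispensing records are gap-adjusted with carry-over
   (early refills start counting when the previous supply runs out; agents
   within the class are pooled, so switching keeps credit), hospital days
   are credited (in-hospital supply is assumed), and PDC is computed per
   90-day window as

   `PDC_k = min(covered days + in-hospital days, 90) / 90`

   then binned into ten ordinal states (1 = 0–9%, …, 10 = 90–100%).

2. **First-order proportional-odds Markov transition model.** For windows
   t = 5…20 (years 2–5), the state `Y_t` follows a cumulative-logit model

   `P(Y_t >= j | x) = logistic(alpha_j + x beta)`,  j = 2…10,

   where `x` contains the previous state `Y_{t-1}` (indicator-coded),
   the window index, restricted-cubic-spline (4-knot) effects of age and
   CHA2DS2-VASc score, and spline effects of the days covered in each of
   the four first-year windows, the third and fourth interacting with
   time. Estimation is by Newton–Raphson on the analytic gradient and
   Hessian (compiled); candidate models are compared by AIC and
   likelihood-ratio tests.

3. **State occupancy probabilities (SOPs).** Recursive matrix
   multiplication unconditions on the previous state:
   `row_t = row_{t-1} P_t`, giving, per patient, the probability of each
   adherence state at every future window, and *mean time in state* (the
   sum of a state's SOPs, in 90-day units).

4. **Diagnostics.** Subject-level, time-stratified, GAM-smoothed and
   one-step transition calibration; discrimination via the SOP
   distribution width (IQR length across patients, bootstrap-validated);
   median absolute error of mean time in the top state.

Because registry claims data cannot be redistributed, the package ships a
synthetic cohort generator with a fully known transition model
(`default_true_model()`); every claim about the pipeline is validated
against that ground truth.

## Worked example

```r
library(pdcmarkov)

coh <- generate_cohort(300, seed = 1)          # synthetic claims
windows <- build_cohort_windows(coh$dispensing, coh$hospital, coh$baseline)
transitions <- build_transition_table(windows, coh$baseline)
fit <- fit_po_markov(final_model_spec(), transitions)
fit
#> Proportional-odds Markov transition model
#>    10 states; 4800 transitions; 43 parameters
#>   log-likelihood: -2482.3235  AIC: 5050.647
#>   converged: TRUE

profile <- data.frame(age = 78, chads_vasc = 5, days_w1 = 90, days_w2 = 90,
                      days_w3 = 85, days_w4 = 85)
s <- compute_sops(fit, profile, initial_state = 10)
round(mean_time_in_state(s, 10), 2)
#> state10
#>   13.36
plot_sops(s)                                   # stacked SOP chart
```

Mean time 13.36 (in 90-day units, out of 16) is this patient's expected
time in the 90–100% adherence state over years 2–5; the same patient with
all four first-year windows fully covered scores higher, reflecting the
steep loss of long-term adherence from missing even a few days per window
in the second half of year 1.

A config-driven pipeline (`run_simulate`, `run_pdc`, `run_fit`,
`run_predict`, `run_evaluate`) writes the CSV/JSON/figure artifacts, and
`inst/cli/pdcmarkov.R` wraps it for shell use.

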