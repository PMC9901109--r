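# wcesurv

Weighted composite endpoint survival analysis for randomized trials with
multiple recurrent events of differing severity.

Fixed-follow-up cardiovascular trials usually analyze a MACE composite —
recurrent myocardial infarction (REMI), congestive heart failure (CHF),
cardiogenic shock (SHK), all-cause death (DTH) — as time to the *first*
event, which throws away every later event and treats a transient
re-infarction like a death. `wcesurv` instead gives each event type a
clinical severity weight `w_k ∈ (0, 1]` (death = 1) and estimates a weighted
product-limit survival curve that uses **all** events of **all** subjects:

* per subject: `S_i(t) = Π_{j: t_j ≤ t} (1 − w_ij)` — each event removes a
  fraction of the subject's remaining survival weight, death removes all of
  it;
* pooled over the `n` enrolled subjects: `S(t) = (1/n) Σ_i S_i(t)`, which is
  identical to a product-limit recursion `S(t_j) = S(t_{j−1})(1 − d_j/n_j)`
  with weighted loss `d_j = Σ_i [S_i(t_{j−1}) − S_i(t_j)]` and weighted risk
  set `n_j = Σ_i S_i(t_{j−1})`;
* variance, from a per-time multinomial event model and the delta method:

      Var(S(t)) ≈ (1/n²) Σ_i S_i²(t) Σ_{j: t_j ≤ t}
                  W'[diag(P_j) − P_j P_j']W / (1 − W'P_j)²,

  with `P_j = E_.j / n_j` the estimated per-type event probabilities, giving
  normal confidence bands `S(t) ± z·sd`.

Setting all weights to 1 and truncating at the first event recovers the
traditional Kaplan-Meier analysis exactly — the package carries that
analysis alongside (`traditional_fit()`) for head-to-head comparison, plus a
calibrated renewal simulator for multiple-recurrent-event trials and a
variance-versus-sample-size experiment harness. The method requires complete
follow-up (every subject observed to the end of the window or to death);
censored data are rejected at the input layer.

Intended users: trial statisticians and methods researchers working with
short fixed-follow-up RCTs and composite outcomes.

## Worked example

A 25-subject synthetic demonstration trial ships with the package
(two arms, 48 events, 30-day follow-up):

```r
library(wcesurv)
trial <- read_trial_table(
  system.file("extdata", "synthetic_trial_25.csv", package = "wcesurv"),
  mace_catalog(), followup = 30)
fit <- wce_fit(trial)
fit
#> Weighted composite endpoint survival fit (95% CI, weighted risk set)
#>   arm control: n = 12, 22 event times, S(28.02) = 0.4363 (0.1696, 0.7029)
#>   arm treatment: n = 13, 26 event times, S(27.55) = 0.4598 (0.1697, 0.7499)
```

Each line is an arm's weighted survival at its last event time with the
normal band. `summary(fit, times = c(10, 20, 30))` tabulates estimate,
variance and band at chosen days; `plot(fit)` draws the step curves with
shaded bands. The comparison harness contrasts the two analyses through
restricted mean survival over the window:

```r
cmp <- compare_endpoints(trial, seed = 1)
cmp
#> Restricted mean survival over [0, 30] days:
#>       method       arm mean_days mean_normalized
#>     weighted treatment     22.61          0.7537
#>     weighted   control     20.15          0.6716
#>  traditional treatment     16.34          0.5445
#>  traditional   control     12.31          0.4104
#>
#> Difference in mean survival (95% CI, bootstrap):
#>       method estimate      se ci_lower ci_upper
#>     weighted  0.08209 0.09335  -0.1009   0.2650
#>  traditional  0.13409 0.13498  -0.1305   0.3986
```

The weighted analysis credits subjects for surviving non-fatal events: its
mean survival is higher than the traditional analysis in both arms, and on
realistically sized trials (1500 per arm) its variance is uniformly smaller —
`variance_experiment()` reproduces that contrast across sample sizes.
`plot(cmp)` shows the two analyses side by side.

Simulating a full trial under the default ASSENT-3-style conditions:

```r
cfg <- calibrate_config(trial_config(), seed = 1)   # fills C and the no-event mean
trial <- simulate_trial(cfg, seed = 7)              # 1500 subjects per arm
```

A thin command-line wrapper with `estimate`, `simulate`, `calibrate`,
`compare` and `experiment` subcommands lives at
`system.file("cli", "wce.R", package = "wcesurv")`; every run writes a
manifest (seed, option values, input checksums) next to its outputs.

See the vignette (`vignettes/weighted-composite-endpoints.Rmd`) for the
model, the variance derivation, the simulator's calibration scheme and the
package's design decisions.

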