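---
title: "Weighted composite endpoints: model, variance, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted composite endpoints: model, variance, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcesurv)
```

## The problem

Cardiovascular trials routinely report a composite endpoint — e.g. the MACE
composite of recurrent myocardial infarction (REMI), congestive heart failure
(CHF), cardiogenic shock (SHK) and all-cause death (DTH) — analyzed as time to
the *first* component event. That analysis discards everything after the
first event and values a transient re-infarction exactly like a death. When
event types differ in clinical severity (asperity), in timing (chronology)
and in treatment response, the first-event reduction is both wasteful and
biased toward the mildest, earliest events.

`wcesurv` implements a weighted product-limit estimator for this setting.
Each event type `k` carries a stakeholder-elicited severity weight
`w_k` in `(0, 1]`, with the terminal type (death) fixed at 1. Weights are
*inputs* — typically from a Delphi panel of clinicians — not estimated
quantities; the package ships the standard MACE set
(`mace_catalog()`: 0.2, 0.3, 0.5, 1.0).

## Estimator

For subject `i` with events at times `t_j` and weights `w_ij`, the subject's
survival path is the product

    S_i(t) = prod_{j : t_j <= t} (1 - w_ij),

a right-continuous step function starting at 1; a death multiplies by 0,
simultaneous events of one subject multiply within a single step. The pooled
estimate over the `n` enrolled subjects (including the event-free ones) is
the mean

    S(t) = (1/n) sum_i S_i(t).

This mean form is identical to a product-limit recursion
`S(t_j) = S(t_{j-1}) (1 - d_j / n_j)` built from the *weighted* increments

    d_j = sum_i [S_i(t_{j-1}) - S_i(t_j)],     n_j = sum_i S_i(t_{j-1}),

which generalize the Kaplan-Meier death count and risk-set size: with all
weights set to 1 and each subject truncated at their first event, `d_j` and
`n_j` are exactly the Kaplan-Meier counts and the estimate is exactly the
unweighted Kaplan-Meier of the first-event time (`traditional_fit()`;
the test suite verifies the equivalence to `1e-12` against the `survival`
package). The mean-form/product-form identity is likewise enforced at
`1e-12` on every dataset the tests touch — the two forms are computed through
independent code paths (`subject_paths()` vs `heuristic_increments()`).

The method assumes **complete follow-up**: a fixed window `[0, tau]` with
every subject observed to `tau` or to death. Right censoring is rejected at
the input layer, by design — short fixed-follow-up randomized trials are the
intended scope. Events of one subject are treated as independent across
episodes, which is what permits the multiplicative path.

## Variance

At each distinct event time `t_j`, a subject at risk experiences event type
`k` with probability `P_jk` (at most one event per subject-time — a
multinomial with one trial over the `K` types plus "no event"). The weighted
event indicator `omega = W'E` then has mean `W'P_j` and variance
`W'[diag(P_j) - P_j P_j'] W` (`omega_moments()`). Estimating `P_j` by
`E_.j / n_j` — typed event counts over the weighted risk set — and combining
subject independence with a delta-method expansion of the product gives

    Var(S(t)) ~ (1/n^2) sum_i S_i^2(t) *
                sum_{j: t_j <= t} W'[diag(P_j) - P_j P_j'] W / (1 - W'P_j)^2.

Confidence bands are the symmetric normal `S(t) ± z * sd`, clipped to
`[0, 1]` for reporting (raw limits are kept in an attribute; the normal
approximation can overshoot near the boundaries).

Design choices worth knowing:

* **Risk-set convention.** `n_j` in `P_j = E_.j / n_j` is the *weighted*
  risk set `sum_i S_i(t_{j-1})`, the same quantity the product-limit
  recursion uses — consistency between the estimate and its variance is the
  rationale. The raw count of not-yet-dead subjects is available as
  `risk.set = "count"` for sensitivity analysis; it is never smaller, so it
  gives slightly smaller hazards and variances.
* **Degenerate hazards.** `W'P_j >= 1` can only occur when the last
  remaining survival weight is wiped out at one time; if subjects remain at
  risk it is an error, otherwise the variance contribution is defined as 0
  (everything that could be lost already has been).
* **Simultaneous same-subject events.** The multinomial(1) model excludes
  them. They are legal input (the estimate handles them multiplicatively),
  counted, and tolerated in the variance while they are rare (< 1% of event
  rows); beyond that the fit refuses rather than silently mis-modelling.
* **Zero-event times** (possible on a user-supplied grid) contribute zero
  variance and are skipped, avoiding 0/0.
* **Numerics.** Paths are accumulated in log space (`log1p(-w)`, with
  `-Inf` cleanly propagating death), so products of hundreds of factors are
  exact to machine precision; identity checks use an absolute tolerance of
  `1e-12`, appropriate for sums/products of well-scaled values.

In the weights-1 reduction the variance becomes
`(S/n) * sum_j h_j / (1 - h_j)` with `h_j` the Kaplan-Meier hazard — the
no-censoring Greenwood form up to the ratio `S(t_{j-1}) / S(t)` inside the
sum. The tests confirm agreement within 10% on death-only data at `n = 200`,
and a 1000-replicate Monte-Carlo check at `n = 1500` finds the analytic
variance of `S(30)` within a few percent of the empirical sampling variance
(the acceptance tolerance is 15%).

## Trial simulator

`simulate_trial()` generates multiple-recurrent-event cohorts by a renewal
scheme: each subject repeatedly draws a category — one of the `K` event
types or "no event" — from a multinomial, and a sojourn time from an
exponential with that category's mean (exponentials are parameterized by
mean, in days). Sojourns accumulate on the subject's clock; an event is
recorded if its cumulative time is within the `tau = 30`-day window; the
clock restarts after every non-fatal episode and the subject stops at death
or when the clock passes `tau`. Continuous times are kept; nothing is
rounded to days.

The default configuration (`trial_config()`) encodes an ASSENT-3-style
two-arm trial of 1500 subjects per arm: treatment-arm 30-day event rates
(REMI 6%, CHF 5%, SHK 4%, DTH 3%), control (3%, 4%, 5%, 6%), mean times to
event (3.0, 2.4, 2.3, 5.5 days), MACE weights. These are the study
conditions; they are not tuning knobs.

Two constants are not trial-reported and must be calibrated:

* **The mean no-event sojourn** `mu_0`. The accounting identity
  `sum_k mu_k + mu_0 = tau - mu_after_death` bounds it analytically
  (`no_event_bounds()`: 15.9–16.8 days for the treatment arm, the extremes
  corresponding to all deaths on the last day vs all at time 0, where
  `mu_after_death = death_rate * tau = 0.9`). `calibrate_no_event_mean()`
  iterates the identity as a fixed point: simulate `m` cohorts at the
  current value, measure the realized mean time after death, update. From a
  start of 1 day it enters the bounds in two steps and converges (tolerance
  0.05 days, damping after six iterations if needed) — to about 16.28 days
  for the treatment arm at `m = 1000`, `n = 1500`.
* **The incident-rate coefficient** `C`. Because events recur, feeding the
  target 30-day rates directly into the multinomial inflates the realized
  rates (a subject gets roughly 2.5 multinomial draws within 30 days under
  these conditions). Incident probabilities are therefore `rate_k / C` with
  a single scalar `C` shared by all types.
  `calibrate_rate_coefficient()` grid-searches `[1, 5]` (coarse 0.1 pass,
  fine 0.01 pass, common random numbers across candidates) minimizing the
  sum of squared differences between realized and target per-type rates.
  "Realized rate" is operationalized as the proportion of subjects with at
  least one event of the type within the window — the definition trial
  reports use. Under the default conditions the minimizer is about 2.65,
  and the realized rates at that value track the targets to within a few
  percent. The minimizer is sensitive to the renewal accounting: variants
  that stop event generation at the first no-event draw, or count events
  rather than subjects, move the effective inflation (and hence `C`)
  anywhere from ~1.1 to ~2.7. The conventions above — full renewal,
  subject-based rates, least squares over all four types — are the
  package's fixed choices.

Since each constant weakly influences the other's calibration, the
`calibrate_config()` wrapper seeds `mu_0` at the analytic midpoint,
calibrates `C`, runs the fixed point at that `C`, then refines `C` once.

**RNG design.** A simulation call consumes one seeded stream, vectorized
across subjects; replicate- and arm-level sub-seeds are derived
deterministically from the user's seed, so a whole trial, a calibration, or
a variance experiment is bit-for-bit reproducible from `(seed, parameters)`
while arms and replicates remain independent.

**What the generator does and does not emulate.** It reproduces per-type
30-day event rates, recurrence, a terminal event, and exponential sojourn
scales. It does not model correlated events or frailty (episodes are drawn
independently — realized per-subject type counts still pick up a small
correlation, |r| < 0.05 under the defaults, purely from the shared 30-day
budget and the death stopping rule), calendar-time rate variation,
censoring, or non-exponential sojourns. Passing tests therefore demonstrate
correctness of the estimator and calibration machinery under these idealized
conditions, not robustness to real-data violations of them.

## Comparison harness

`compare_endpoints()` runs both analyses on a two-arm trial and summarizes
each arm by restricted mean survival — the area under the step curve over
`[0, tau]`, reported both in days and divided by `tau` (the headline,
probability-scale figure). "Mean survival" has no unique definition over a
fixed window; the restricted mean is the standard choice and, because the
pooled curve is the mean of subject paths, it equals the average of
per-subject restricted means. That identity makes the between-arm difference
a difference of two independent sample means, so its interval comes either
from a subject-level bootstrap (default, 1000 resamples, seeded) or from the
analytic `var(auc_i)/n` formula; the two agree closely and the bootstrap is
the default only because it is equally cheap and makes fewer approximations.

`variance_experiment()` reproduces the precision contrast: for each sample
size it simulates replicate cohorts, fits both estimators, evaluates the
analytic variance at days 1–30, and averages over replicates. Under the
default conditions the weighted method's variance is below the traditional
one at every day and every size — the weighted estimator spreads subject
contributions over `(0, 1)` instead of concentrating them on {0, 1}, and
pointwise its survival estimate is never below the traditional one (a first
non-fatal event removes only part of a subject's weight).

## Problem sizes used by the checks

The package's own test suite runs the full-scale checks it reports:
calibration at `m = 1000` cohorts of `n = 1500`; the Monte-Carlo variance
oracle over 1000 replicates of `n = 1500`; the precision sweep at
`n in {250, 500, 1000}` with 25 replicates (the sweep is monotone and can be
extended to larger sizes by the user through `variance_experiment()`).
Smaller property checks use seeded cohorts of 35–1800 subjects.

## Known limitations

* No right censoring, left truncation, interval censoring, or time-varying
  covariates — complete fixed-window follow-up is a hard requirement.
* No regression structure (no hazard ratios, no covariates); the output is
  a pair of curves and a mean-survival contrast.
* The variance is a large-sample delta-method approximation; bands are
  pointwise, not simultaneous, with no log-log or arcsine transform.
* Severity weights are taken as known constants; uncertainty in the weights
  themselves is not propagated.
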