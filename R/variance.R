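#' Per-time event-type probability profile
#'
#' At each pooled event time `t_j` the vector of event-type counts `E_.j`
#' (one component per catalog type) is divided by the risk-set size `n_j` to
#' give the maximum-likelihood event-type probabilities `P_j = E_.j / n_j`
#' of the per-time multinomial(1) event model. `W'P_j` is the weighted
#' analogue of the Kaplan-Meier hazard `d_j / n_j` and reduces to it exactly
#' when all weights are 1.
#'
#' @inheritParams subject_paths
#' @param risk.set `"weighted"` for `n_j = sum_i S_i(t_{j-1})` (the
#'   convention consistent with the product-limit identity) or `"count"` for
#'   the raw number of not-yet-dead subjects.
#' @return Object of class `wce_event_profile`: list with `time`, `counts`
#'   (J-by-K matrix `E_.j`), `n_risk`, `P` (J-by-K matrix), `types`.
#' @export
estimate_event_probs <- function(trial, arm = NULL,
                                 risk.set = c("weighted", "count")) {
  risk.set <- match.arg(risk.set)
  arm <- resolve_arm(trial, arm)
  catalog <- attr(trial, "catalog")
  ev <- arm_events(trial, arm)
  grid <- sort(unique(ev$time))
  J <- length(grid)
  K <- nrow(catalog)
  Emat <- matrix(0, J, K, dimnames = list(NULL, catalog$event_type))
  if (J) {
    j <- match(ev$time, grid)
    cnt <- table(factor(j, levels = seq_len(J)),
                 factor(ev$k, levels = seq_len(K)))
    Emat[] <- as.numeric(cnt)
  }
  if (risk.set == "weighted") {
    p <- subject_paths(trial, arm)
    Ssum <- colSums(p$S)
    n_risk <- c(p$n, Ssum[-J])[seq_len(J)]
  } else {
    n_risk <- count_risk_set(ev, grid, ev$n)
  }
  if (any(n_risk <= 0 & rowSums(Emat) > 0))
    stop("events recorded at a time with empty risk set")
  structure(list(time = grid, counts = Emat, n_risk = n_risk,
                 P = Emat / pmax(n_risk, .Machine$double.xmin),
                 types = catalog$event_type, n = ev$n),
            class = "wce_event_profile")
}

#' Moments of the per-time weighted event indicator
#'
#' For one subject at one event time, the weighted event indicator is
#' `omega = W'E` where `E` is multinomial(1) over the `K` event types with
#' probability vector `p` (remaining mass = no event). Its moments are
#' `E[omega] = W'p` and `Var(omega) = W' (diag(p) - p p') W`, which the
#' survival-variance approximation accumulates over event times.
#'
#' @param p probability vector over the `K` event types; `sum(p) <= 1`.
#' @param w weight vector of length `K`.
#' @return Named numeric vector `c(mean, variance)`.
#' @examples
#' omega_moments(c(0, 0, 0, 0.1), c(0.2, 0.3, 0.5, 1.0))  # Bernoulli death
#' @export
omega_moments <- function(p, w) {
  if (length(p) != length(w)) stop_validation("`p` and `w` lengths differ")
  if (any(p < 0) || sum(p) > 1 + 1e-12)
    stop_validation("`p` must be non-negative with sum <= 1")
  m <- sum(w * p)
  c(mean = m, variance = sum(w^2 * p) - m^2)
}

#' Delta-method variance of the pooled weighted survival estimate
#'
#' Implements the large-sample approximation
#' `Var(S(t)) ~ (1/n^2) sum_i S_i^2(t) * sum_{j: t_j <= t}
#'   W'[diag(P_j) - P_j P_j'] W / (1 - W'P_j)^2`,
#' obtained from the independence of subjects and a delta-method expansion of
#' the per-subject event products under the multinomial event model. Times
#' with no events contribute nothing; subjects whose path has reached 0
#' contribute nothing.
#'
#' @param paths a [subject_paths()] object.
#' @param profile a [estimate_event_probs()] object on the same grid.
#' @param weights catalog weight vector `W`.
#' @return Numeric vector of variances, one per grid time.
#' @export
survival_variance <- function(paths, profile, weights) {
  stopifnot(inherits(paths, "wce_paths"), inherits(profile, "wce_event_profile"))
  if (!isTRUE(all.equal(paths$grid, profile$time)))
    stop_validation("`paths` and `profile` are not on the same grid")
  W <- as.numeric(weights)
  wtp <- as.vector(profile$P %*% W)
  vw <- as.vector(profile$P %*% W^2) - wtp^2
  S2sum <- colSums(paths$S^2)
  degen <- wtp >= 1
  if (any(degen & S2sum > 1e-12))
    stop("W'P_j >= 1 at an event time while subjects remain at risk")
  v <- ifelse(degen, 0, vw / (1 - wtp)^2)
  S2sum * cumsum(v) / paths$n^2
}

#' Normal-approximation confidence band
#'
#' Symmetric band `estimate +/- z * sqrt(variance)` with the standard-normal
#' quantile for the requested level. Reported limits are clipped to `[0, 1]`
#' (the normal approximation can overshoot near the boundaries); the raw
#' limits are returned alongside.
#'
#' @param estimate survival estimates per grid time.
#' @param variance variances per grid time.
#' @param level confidence level in (0, 1), default 0.95.
#' @return Data frame with columns `ci_lower`, `ci_upper` (clipped),
#'   `ci_lower_raw`, `ci_upper_raw`.
#' @export
confidence_band <- function(estimate, variance, level = 0.95) {
  if (level <= 0 || level >= 1) stop_validation("`level` must be in (0, 1)")
  if (any(variance < 0)) stop_validation("negative variance")
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(variance)
  data.frame(ci_lower = pmax(0, estimate - z * se),
             ci_upper = pmin(1, estimate + z * se),
             ci_lower_raw = estimate - z * se,
             ci_upper_raw = estimate + z * se)
}
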