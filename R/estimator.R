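#' Per-subject weighted survival paths
#'
#' Each subject's survival path starts at 1 and, at every event time, is
#' multiplied by `1 - w` for the weight `w` of the event; simultaneous events
#' of one subject multiply in a single step. A terminal event (weight 1)
#' drops the path to exactly 0. Paths are right-continuous step functions:
#' the value reported at a grid time already includes events at exactly that
#' time.
#'
#' @param trial a [wce_trial()].
#' @param arm arm label; defaults to the only arm (error if several).
#' @param grid optional evaluation grid; defaults to the arm's pooled distinct
#'   event times.
#' @return A list of class `wce_paths` with elements `grid` (ordered distinct
#'   event times), `S` (n-by-J matrix of path values at the grid times),
#'   `subject_id`, `n`, and `followup`.
#' @export
subject_paths <- function(trial, arm = NULL, grid = NULL) {
  arm <- resolve_arm(trial, arm)
  ev <- arm_events(trial, arm)
  if (is.null(grid)) grid <- sort(unique(ev$time))
  grid <- sort(unique(as.numeric(grid)))
  S <- path_matrix(ev$i, ev$time, ev$w, ev$n, grid)
  structure(list(grid = grid, S = S, subject_id = ev$ids, n = ev$n,
                 followup = attr(trial, "followup"), arm = arm),
            class = "wce_paths")
}

# Dense n-by-J matrix of per-subject path values. Events are binned to the
# first grid point >= their time (exact matches when the grid is the pooled
# event-time set). Log-space accumulation keeps products of many factors
# exact to machine precision; log(0) = -Inf propagates a terminal event.
path_matrix <- function(i, time, w, n, grid) {
  J <- length(grid)
  if (J == 0L) return(matrix(1, n, 0))
  F <- matrix(0, n, J)
  if (length(i)) {
    j <- findInterval(time, grid, left.open = TRUE) + 1L
    if (any(j > J)) stop("event time beyond the last grid point")
    lf <- rowsum(log1p(-w), group = (j - 1L) * n + i)
    cell <- as.integer(rownames(lf))
    F[cell] <- lf
  }
  if (J == 1L) exp(F) else exp(t(apply(F, 1L, cumsum)))
}

resolve_arm <- function(trial, arm) {
  arms <- unique(trial$arm)
  if (is.null(arm)) {
    if (length(arms) > 1)
      stop_validation(sprintf("trial has arms %s; specify `arm`",
                              paste(arms, collapse = ", ")))
    return(arms)
  }
  if (!arm %in% arms) stop_validation(sprintf("no arm '%s' in trial", arm))
  arm
}

#' Heuristic product-limit increments
#'
#' The weighted analogue of the Kaplan-Meier death and risk-set counts:
#' at each pooled event time `t_j`,
#' `d_j = sum_i [S_i(t_{j-1}) - S_i(t_j)]` is the survival weight lost and
#' `n_j = sum_i S_i(t_{j-1})` is the weighted risk set just before `t_j`.
#' The pooled estimate obeys the product-limit recursion
#' `S(t_j) = S(t_{j-1}) (1 - d_j / n_j)`, which coincides with the mean of
#' the subject paths. With all weights 1 and subjects truncated at their
#' first event, `d_j` and `n_j` reduce to the standard Kaplan-Meier counts.
#'
#' @inheritParams subject_paths
#' @return Data frame with columns `time`, `d`, `n_risk`, `hazard`.
#' @export
heuristic_increments <- function(trial, arm = NULL) {
  p <- subject_paths(trial, arm)
  increments_from_sums(p$grid, colSums(p$S), p$n)
}

increments_from_sums <- function(grid, Ssum, n) {
  prev <- c(n, Ssum[-length(Ssum)])[seq_along(Ssum)]
  if (length(Ssum) == 0) prev <- numeric(0)
  data.frame(time = grid, d = prev - Ssum, n_risk = prev,
             hazard = ifelse(prev > 0, (prev - Ssum) / prev, 0))
}

#' Weighted composite endpoint survival fit
#'
#' Fits the weighted product-limit survival curve for each arm of a trial:
#' the pooled estimate at time `t` is the mean over all `n` subjects of the
#' per-subject weighted paths ([subject_paths()]), together with the
#' delta-method variance under a per-time multinomial event model
#' ([survival_variance()]) and symmetric normal confidence bands.
#'
#' `method = "first.event"` reduces each subject to their first event with
#' weight forced to 1, which reproduces the traditional time-to-first-event
#' Kaplan-Meier analysis as a special case (see [traditional_fit()]).
#'
#' @param trial a [wce_trial()].
#' @param conf.level confidence level for the normal band (default 0.95).
#' @param risk.set risk-set convention for the per-time event-type
#'   probabilities used by the variance: `"weighted"` (default) uses the
#'   weighted risk set `n_j = sum_i S_i(t_{j-1})`; `"count"` uses the raw
#'   number of subjects not yet dead, exposed for sensitivity analysis.
#' @param method `"weighted"` (the composite estimator) or `"first.event"`
#'   (traditional analysis).
#' @return Object of class `wce_fit`: list with `curves` (named per-arm data
#'   frames with columns `time`, `estimate`, `variance`, `std.err`,
#'   `ci_lower`, `ci_upper`, `n_risk`, including a `time = 0` anchor row),
#'   `n` (subjects per arm), plus the call settings. Confidence limits are
#'   clipped to `[0, 1]`; unclipped values are kept in the `ci_raw`
#'   attribute of each curve.
#' @examples
#' cat <- mace_catalog()
#' tab <- data.frame(
#'   subject_id = c("a", "a", "b", "c"), arm = "x",
#'   time = c(3, 8, 30, 5), event_type = c("SHK", "CHF", "NONE", "DTH"))
#' fit <- wce_fit(wce_trial(tab, cat, 30))
#' fit$curves$x
#' @export
wce_fit <- function(trial, conf.level = 0.95,
                    risk.set = c("weighted", "count"),
                    method = c("weighted", "first.event")) {
  stopifnot(inherits(trial, "wce_trial"))
  risk.set <- match.arg(risk.set)
  method <- match.arg(method)
  if (conf.level <= 0 || conf.level >= 1)
    stop_validation("`conf.level` must be in (0, 1)")
  catalog <- attr(trial, "catalog")
  arms <- unique(trial$arm)
  curves <- lapply(arms, function(a) {
    ev <- arm_events(trial, a)
    if (method == "first.event")
      ev <- first_event_only(ev, which(catalog$terminal))
    arm_curve(ev, catalog, conf.level, risk.set)
  })
  names(curves) <- arms
  structure(list(
    curves = curves,
    n = setNames(vapply(curves, function(cv) attr(cv, "n"), 0L), arms),
    method = method, risk.set = risk.set, conf.level = conf.level,
    catalog = catalog, followup = attr(trial, "followup")
  ), class = "wce_fit")
}

#' Traditional time-to-first-event fit
#'
#' Convenience wrapper: [wce_fit()] with `method = "first.event"`. Every
#' subject is truncated at their first event, which is given full weight 1
#' regardless of type; with complete follow-up the estimate equals the
#' empirical survival function of the first-event time (the unweighted
#' Kaplan-Meier without censoring).
#'
#' @inheritParams wce_fit
#' @export
traditional_fit <- function(trial, conf.level = 0.95,
                            risk.set = c("weighted", "count")) {
  wce_fit(trial, conf.level, risk.set, method = "first.event")
}

# Reduce to the traditional composite: each subject's first event, any type,
# becomes a full-weight terminal event (k remapped so the variance model sees
# a single composite event type of weight 1).
first_event_only <- function(ev, terminal_k) {
  if (!length(ev$i)) return(ev)
  keep <- which(!duplicated(ev$i))  # events are in per-subject time order
  list(i = ev$i[keep], time = ev$time[keep],
       k = rep(terminal_k, length(keep)), w = rep(1, length(keep)),
       term = rep(TRUE, length(keep)), n = ev$n, ids = ev$ids)
}

# Core per-arm computation. Only subjects with events need a path matrix;
# event-free subjects contribute constant 1 to every pooled sum.
arm_curve <- function(ev, catalog, conf.level, risk.set) {
  n <- ev$n
  if (n == 0) stop_validation("arm has no subjects")
  W <- catalog$weight
  K <- length(W)
  grid <- sort(unique(ev$time))
  J <- length(grid)
  z <- qnorm(1 - (1 - conf.level) / 2)

  if (J == 0L) {
    cv <- data.frame(time = 0, estimate = 1, variance = 0, std.err = 0,
                     ci_lower = 1, ci_upper = 1, n_risk = n)
    attr(cv, "ci_raw") <- cv[, c("time", "ci_lower", "ci_upper")]
    attr(cv, "n") <- n
    attr(cv, "n_simultaneous") <- 0L
    return(cv)
  }

  eu <- sort(unique(ev$i))
  ii <- match(ev$i, eu)
  Se <- path_matrix(ii, ev$time, ev$w, length(eu), grid)
  free <- n - length(eu)
  Ssum <- colSums(Se) + free
  S2sum <- colSums(Se^2) + free
  est <- Ssum / n
  Sprev <- c(n, Ssum[-J])

  # simultaneous same-subject events violate the multinomial(1) moment model;
  # tolerated while rare, rejected when they would distort the variance
  j <- match(ev$time, grid)
  n_sim <- sum(duplicated(cbind(ev$i, j)))
  if (n_sim / length(ev$i) >= 0.01)
    stop_validation(sprintf(
      "%d of %d event rows are simultaneous same-subject events (>= 1%%); the multinomial event model does not cover them",
      n_sim, length(ev$i)))

  Emat <- matrix(0, J, K)
  cnt <- table(factor(j, levels = seq_len(J)), factor(ev$k, levels = seq_len(K)))
  Emat[] <- as.numeric(cnt)
  n_risk <- if (risk.set == "weighted") Sprev else count_risk_set(ev, grid, n)
  if (any(n_risk <= 0 & rowSums(Emat) > 0))
    stop("events recorded at a time with empty risk set")
  P <- Emat / n_risk
  wtp <- as.vector(P %*% W)
  vw <- as.vector(P %*% W^2) - wtp^2
  degen <- wtp >= 1
  if (any(degen & S2sum > 1e-12))
    stop(paste("W'P_j >= 1 at an event time while subjects remain at risk;",
               "the variance approximation is undefined there"))
  v <- ifelse(degen, 0, vw / (1 - wtp)^2)
  variance <- S2sum * cumsum(v) / n^2
  se <- sqrt(variance)
  lo_raw <- est - z * se
  hi_raw <- est + z * se

  cv <- data.frame(
    time = c(0, grid),
    estimate = c(1, est),
    variance = c(0, variance),
    std.err = c(0, se),
    ci_lower = pmax(0, c(1, lo_raw)),
    ci_upper = pmin(1, c(1, hi_raw)),
    n_risk = c(n, n_risk)
  )
  attr(cv, "ci_raw") <- data.frame(time = c(0, grid), ci_lower = c(1, lo_raw),
                                   ci_upper = c(1, hi_raw))
  attr(cv, "n") <- n
  attr(cv, "n_simultaneous") <- n_sim
  cv
}

# raw-count risk set: subjects not yet dead strictly before each grid time
count_risk_set <- function(ev, grid, n) {
  J <- length(grid)
  dt <- ev$time[ev$term]
  if (!length(dt)) return(rep(n, J))
  dead_before <- vapply(grid, function(t) sum(dt < t), 0)
  n - dead_before
}

#' @export
print.wce_fit <- function(x, ...) {
  cat(sprintf("%s survival fit (%d%% CI, %s risk set)\n",
              if (x$method == "weighted") "Weighted composite endpoint"
              else "Traditional time-to-first-event",
              round(100 * x$conf.level), x$risk.set))
  for (a in names(x$curves)) {
    cv <- x$curves[[a]]
    last <- cv[nrow(cv), ]
    cat(sprintf(
      "  arm %s: n = %d, %d event times, S(%g) = %.4f (%.4f, %.4f)\n",
      a, x$n[[a]], nrow(cv) - 1L, last$time, last$estimate,
      last$ci_lower, last$ci_upper))
  }
  invisible(x)
}

#' @export
summary.wce_fit <- function(object, times = NULL, ...) {
  out <- lapply(names(object$curves), function(a) {
    cv <- object$curves[[a]]
    if (!is.null(times)) {
      idx <- findInterval(times, cv$time)
      cv <- cv[pmax(idx, 1L), , drop = FALSE]
      cv$time <- times
    }
    cbind(arm = a, cv)
  })
  do.call(rbind, out)
}

#' Export fitted curves to CSV
#'
#' One row per (arm, grid time) with columns
#' `arm,time,estimate,variance,ci_lower,ci_upper,n_effective`; the companion
#' format consumed by the plotting and comparison layers.
#'
#' @param fit a [wce_fit()].
#' @param path file path.
#' @export
write_curves <- function(fit, path) {
  stopifnot(inherits(fit, "wce_fit"))
  tab <- do.call(rbind, lapply(names(fit$curves), function(a) {
    cv <- fit$curves[[a]]
    data.frame(arm = a, time = cv$time, estimate = cv$estimate,
               variance = cv$variance, ci_lower = cv$ci_lower,
               ci_upper = cv$ci_upper, n_effective = cv$n_risk)
  }))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
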