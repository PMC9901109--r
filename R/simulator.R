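#' Configuration of a multiple-recurrent-event trial simulation
#'
#' Bundles everything the renewal simulator needs: per-arm target 30-day
#' event rates (the proportion of subjects with at least one event of each
#' type within follow-up), mean times to each event type, the event catalog
#' with severity weights, the follow-up length, and — per arm — the mean
#' no-event sojourn time and the incident-rate coefficient `C` produced by
#' [calibrate_no_event_mean()] and [calibrate_rate_coefficient()].
#'
#' The defaults are the ASSENT-3-style MACE trial conditions: 1500 subjects
#' per arm followed 30 days; treatment rates (REMI 6%, CHF 5%, SHK 4%,
#' DTH 3%), control rates (3%, 4%, 5%, 6%); mean times to event (3.0, 2.4,
#' 2.3, 5.5) days; weights from [mace_catalog()].
#'
#' @param rates named list (one element per arm) of per-type target event
#'   rates, each a vector over the catalog types in catalog order.
#' @param mean_times mean time to each event type, days (catalog order).
#' @param catalog an [event_catalog()].
#' @param followup follow-up length, days.
#' @param n subjects per arm.
#' @param no_event_mean named numeric (per arm) mean no-event sojourn, days;
#'   `NA` means not yet calibrated.
#' @param rate_coefficient named numeric (per arm) incident-rate coefficient
#'   `C >= 1`; the per-draw incident probability of type `k` is `rate_k / C`.
#'   `NA` means not yet calibrated.
#' @return Object of class `wce_trial_config`.
#' @seealso [calibrate_config()] to fill in both calibrated constants,
#'   [simulate_trial()] to generate a trial table.
#' @export
trial_config <- function(
    rates = list(treatment = c(REMI = 0.06, CHF = 0.05, SHK = 0.04, DTH = 0.03),
                 control   = c(REMI = 0.03, CHF = 0.04, SHK = 0.05, DTH = 0.06)),
    mean_times = c(REMI = 3.0, CHF = 2.4, SHK = 2.3, DTH = 5.5),
    catalog = mace_catalog(),
    followup = 30,
    n = 1500,
    no_event_mean = NULL,
    rate_coefficient = NULL) {
  stopifnot(inherits(catalog, "wce_catalog"))
  K <- nrow(catalog)
  arms <- names(rates)
  if (is.null(arms) || any(arms == ""))
    stop_validation("`rates` must be a named list, one element per arm")
  for (a in arms) {
    r <- rates[[a]]
    if (length(r) != K)
      stop_validation(sprintf("arm '%s': need %d rates (one per catalog type)", a, K))
    if (any(r < 0) || any(r >= 1) || sum(r) >= 1)
      stop_validation(sprintf("arm '%s': rates must be in [0,1) and sum to < 1", a))
    rates[[a]] <- setNames(as.numeric(r), catalog$event_type)
  }
  if (length(mean_times) != K || any(mean_times <= 0))
    stop_validation("`mean_times` must be positive, one per catalog type")
  if (followup <= 0) stop_validation("`followup` must be positive")
  if (n < 1) stop_validation("`n` must be at least 1")
  fill <- function(x) {
    out <- setNames(rep(NA_real_, length(arms)), arms)
    if (!is.null(x)) out[names(x)] <- as.numeric(x)
    out
  }
  no_event_mean <- fill(no_event_mean)
  rate_coefficient <- fill(rate_coefficient)
  if (any(!is.na(rate_coefficient) & rate_coefficient < 1))
    stop_validation("`rate_coefficient` must be >= 1")
  if (any(!is.na(no_event_mean) & no_event_mean <= 0))
    stop_validation("`no_event_mean` must be positive")
  structure(list(
    arms = arms, rates = rates,
    mean_times = setNames(as.numeric(mean_times), catalog$event_type),
    catalog = catalog, followup = followup, n = n,
    no_event_mean = no_event_mean, rate_coefficient = rate_coefficient
  ), class = "wce_trial_config")
}

#' @export
print.wce_trial_config <- function(x, ...) {
  cat("Trial simulation config:", x$followup, "days follow-up,", x$n,
      "subjects/arm\n")
  for (a in x$arms)
    cat(sprintf("  %s: rates (%s), C = %s, no-event mean = %s\n", a,
                paste(sprintf("%s %.3g", names(x$rates[[a]]), x$rates[[a]]),
                      collapse = ", "),
                format(x$rate_coefficient[[a]], digits = 4),
                format(x$no_event_mean[[a]], digits = 4)))
  cat("  mean times to event:",
      paste(sprintf("%s %.3g", names(x$mean_times), x$mean_times),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a simulation config as YAML
#'
#' @param path file path.
#' @return `read_trial_config` returns a `wce_trial_config`.
#' @export
read_trial_config <- function(path) {
  y <- yaml::read_yaml(path)
  cat_df <- do.call(rbind, lapply(y$catalog, as.data.frame))
  catalog <- event_catalog(cat_df$event_type, cat_df$weight,
                           cat_df$event_type[as.logical(cat_df$terminal)])
  trial_config(
    rates = lapply(y$rates, unlist),
    mean_times = unlist(y$mean_times),
    catalog = catalog,
    followup = y$followup %||% 30,
    n = y$n %||% 1500,
    no_event_mean = if (!is.null(y$no_event_mean)) unlist(y$no_event_mean),
    rate_coefficient = if (!is.null(y$rate_coefficient)) unlist(y$rate_coefficient)
  )
}

#' @rdname read_trial_config
#' @param config a `wce_trial_config`.
#' @export
write_trial_config <- function(config, path) {
  stopifnot(inherits(config, "wce_trial_config"))
  cl <- config$catalog
  yaml::write_yaml(list(
    rates = lapply(config$rates, as.list),
    mean_times = as.list(config$mean_times),
    catalog = lapply(seq_len(nrow(cl)), function(i)
      list(event_type = cl$event_type[i], weight = cl$weight[i],
           terminal = cl$terminal[i])),
    followup = config$followup, n = config$n,
    no_event_mean = as.list(config$no_event_mean),
    rate_coefficient = as.list(config$rate_coefficient)
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

arm_params <- function(config, arm, require_calibrated = TRUE) {
  if (!arm %in% config$arms)
    stop_validation(sprintf("no arm '%s' in config", arm))
  C <- config$rate_coefficient[[arm]]
  mu0 <- config$no_event_mean[[arm]]
  if (require_calibrated && (is.na(C) || is.na(mu0)))
    stop_validation(sprintf(
      "arm '%s' is not calibrated; run calibrate_config() first (or set no_event_mean and rate_coefficient)",
      arm))
  q <- config$rates[[arm]] / C
  if (!is.na(C) && sum(q) >= 1)
    stop_validation("incident probabilities rates/C must sum to < 1")
  list(q = q, mu = config$mean_times, mu0 = mu0, C = C,
       tau = config$followup,
       term = which(config$catalog$terminal))
}

# Vectorized renewal simulation of one cohort. Each subject repeatedly draws
# a category (K event types + no-event) from the incident multinomial and a
# sojourn from the exponential with that category's mean; sojourns accumulate
# on the subject's clock. An event is recorded when the category is an event
# type and the cumulative time is still within follow-up; the subject stops
# at death or when the clock passes follow-up.
sim_renewal <- function(n, q, mu, mu0, tau, term) {
  K <- length(q)
  probs <- c(q, 1 - sum(q))
  means <- c(mu, mu0)
  active <- seq_len(n)
  clock <- numeric(n)
  death <- rep(NA_real_, n)
  ids <- vector("list", 64L); tms <- vector("list", 64L)
  kks <- vector("list", 64L); r <- 0L
  while (length(active)) {
    m <- length(active)
    cat <- sample.int(K + 1L, m, replace = TRUE, prob = probs)
    tt <- clock[active] + rexp(m, rate = 1 / means[cat])
    rec <- cat <= K & tt <= tau
    if (any(rec)) {
      r <- r + 1L
      ids[[r]] <- active[rec]; tms[[r]] <- tt[rec]; kks[[r]] <- cat[rec]
    }
    died <- rec & cat == term
    death[active[died]] <- tt[died]
    clock[active] <- tt
    active <- active[!(died | tt > tau)]
  }
  list(i = as.integer(unlist(ids[seq_len(r)])),
       time = as.numeric(unlist(tms[seq_len(r)])),
       k = as.integer(unlist(kks[seq_len(r)])), death = death, n = n)
}

#' Draw simulated subject histories for one arm
#'
#' Low-level access to the renewal scheme; [simulate_trial()] is the usual
#' entry point. Randomness comes from the global RNG unless `seed` is given.
#'
#' @param config a calibrated [trial_config()].
#' @param arm arm label.
#' @param n number of subjects (default `config$n`).
#' @param seed optional integer seed.
#' @return List with `events` (data frame `i`, `time`, `event_type`),
#'   `death_time` (per-subject, `NA` if alive at the end) and `n`.
#' @export
draw_subjects <- function(config, arm, n = config$n, seed = NULL) {
  p <- arm_params(config, arm)
  with_seed(seed, {
    s <- sim_renewal(n, p$q, p$mu, p$mu0, p$tau, p$term)
    list(events = data.frame(
           i = s$i, time = s$time,
           event_type = config$catalog$event_type[s$k],
           stringsAsFactors = FALSE),
         death_time = s$death, n = n)
  })
}

#' Simulate a complete two-arm (or multi-arm) trial table
#'
#' Simulates every configured arm independently with the renewal scheme and
#' returns a validated [wce_trial()]; event-free subjects get their `"NONE"`
#' roster row so the sample size is carried by the table.
#'
#' @param config a calibrated [trial_config()].
#' @param seed optional integer seed; arm-level sub-seeds are derived from it
#'   so the output is reproducible as a whole.
#' @param n subjects per arm (default `config$n`).
#' @return A `wce_trial`.
#' @export
simulate_trial <- function(config, seed = NULL, n = config$n) {
  stopifnot(inherits(config, "wce_trial_config"))
  tabs <- lapply(seq_along(config$arms), function(ai) {
    a <- config$arms[[ai]]
    s <- draw_subjects(config, a, n = n,
                       seed = if (!is.null(seed)) derive_seed(seed, ai))
    ids <- sprintf("%s_%05d", a, seq_len(n))
    ev <- s$events
    tab <- data.frame(subject_id = ids[ev$i], arm = rep(a, nrow(ev)),
                      time = ev$time, event_type = ev$event_type,
                      stringsAsFactors = FALSE)
    free <- setdiff(seq_len(n), unique(ev$i))
    if (length(free))
      tab <- rbind(tab, data.frame(subject_id = ids[free], arm = a,
                                   time = config$followup, event_type = "NONE",
                                   stringsAsFactors = FALSE))
    tab
  })
  wce_trial(do.call(rbind, tabs), config$catalog, config$followup)
}

#' Realized 30-day event rates of the simulator
#'
#' Simulates `m` cohorts of `n` subjects and returns, per event type, the
#' proportion of subjects with at least one event of that type within
#' follow-up (the operational definition of a trial event rate), averaged
#' over cohorts.
#'
#' @inheritParams draw_subjects
#' @param m number of cohorts.
#' @param chunk maximum subjects simulated per internal batch.
#' @return Named numeric vector of per-type realized event rates, with the
#'   mean realized time after death (days, averaged over all subjects) in
#'   attribute `after_death`.
#' @export
realized_event_rates <- function(config, arm, m = 100, n = config$n,
                                 seed = NULL, chunk = 500000L) {
  p <- arm_params(config, arm)
  K <- nrow(config$catalog)
  total <- m * n
  done <- 0
  hits <- numeric(K)
  after <- 0
  b <- 0L
  while (done < total) {
    nb <- min(chunk, total - done)
    b <- b + 1L
    s <- with_seed(if (!is.null(seed)) derive_seed(seed, b),
                   sim_renewal(nb, p$q, p$mu, p$mu0, p$tau, p$term))
    for (k in seq_len(K))
      hits[k] <- hits[k] + length(unique(s$i[s$k == k]))
    after <- after + sum(p$tau - s$death[!is.na(s$death)])
    done <- done + nb
  }
  structure(setNames(hits / total, config$catalog$event_type),
            after_death = after / total)
}

#' Analytic bounds on the mean no-event sojourn
#'
#' The accounting identity
#' `sum_k mu_k + mu_no_event = followup - mu_after_death`
#' pins the mean no-event sojourn between two extremes of the time spent
#' after death: if every death falls on the last day, `mu_after_death = 0`
#' and the upper bound is `followup - sum_k mu_k`; if every death falls at
#' time 0, `mu_after_death = death_rate * followup`, giving the lower bound.
#'
#' @inheritParams draw_subjects
#' @return Named vector `c(lower, upper)` (days) with attribute
#'   `after_death_extremes`.
#' @export
no_event_bounds <- function(config, arm) {
  stopifnot(inherits(config, "wce_trial_config"))
  if (!arm %in% config$arms) stop_validation(sprintf("no arm '%s'", arm))
  tau <- config$followup
  smu <- sum(config$mean_times)
  death_rate <- config$rates[[arm]][which(config$catalog$terminal)]
  upper <- tau - smu
  lower <- tau - death_rate * tau - smu
  if (upper <= 0 || lower <= 0)
    stop_validation("mean event times exceed the follow-up window")
  structure(c(lower = unname(lower), upper = unname(upper)),
            after_death_extremes = c(all_deaths_last_day = 0,
                                     all_deaths_at_zero = unname(death_rate * tau)))
}

#' Calibrate the mean no-event sojourn by fixed-point iteration
#'
#' The renewal simulator needs the mean of the no-event sojourn, which is not
#' a trial-reported quantity. It is recovered from the accounting identity
#' (see [no_event_bounds()]): given a current value, `m` cohorts of `n`
#' subjects are simulated, the realized mean time after death is measured,
#' and the next value is `followup - after_death - sum_k mu_k`; iteration
#' stops when successive values differ by less than `tol`. If the raw
#' iteration oscillates, later steps are damped by averaging.
#'
#' @inheritParams realized_event_rates
#' @param start starting value, days (default 1).
#' @param tol convergence tolerance, days.
#' @param max_iter iteration cap; exceeding it is an error (the trace is in
#'   the condition message).
#' @return List of class `wce_calibration` with `value`, `trace`,
#'   `iterations`, `converged`, `bounds`.
#' @export
calibrate_no_event_mean <- function(config, arm = "treatment", m = 1000,
                                    n = 1500, start = 1, tol = 0.05,
                                    max_iter = 25, seed = NULL) {
  stopifnot(inherits(config, "wce_trial_config"))
  b <- no_event_bounds(config, arm)
  cfg <- config
  cur <- start
  trace <- cur
  for (it in seq_len(max_iter)) {
    cfg$no_event_mean[[arm]] <- cur
    rr <- realized_event_rates(cfg, arm, m = m, n = n,
                               seed = if (!is.null(seed)) seed + it)
    nxt <- cfg$followup - attr(rr, "after_death") - sum(cfg$mean_times)
    if (it > 6) nxt <- (cur + nxt) / 2  # damp if slow to settle
    trace <- c(trace, nxt)
    if (abs(nxt - cur) < tol) {
      return(structure(list(value = nxt, trace = trace, iterations = it,
                            converged = TRUE, bounds = b, arm = arm),
                       class = "wce_calibration"))
    }
    cur <- nxt
  }
  stop(sprintf(
    "no-event mean calibration did not converge in %d iterations; trace: %s",
    max_iter, paste(format(trace, digits = 4), collapse = " -> ")))
}

#' @export
print.wce_calibration <- function(x, ...) {
  cat(sprintf("Calibrated no-event mean (arm %s): %.3f days in %d iterations\n",
              x$arm, x$value, x$iterations))
  cat("  bounds:", format(x$bounds["lower"]), "-", format(x$bounds["upper"]),
      "\n  trace:", paste(format(x$trace, digits = 4), collapse = " -> "), "\n")
  invisible(x)
}

#' Calibrate the incident-rate coefficient C
#'
#' With recurrence, feeding trial event rates directly into the renewal
#' multinomial inflates the realized 30-day rates; incident probabilities are
#' therefore the target rates divided by a single coefficient `C`. The
#' calibration searches `interval` for the `C` minimizing the sum of squared
#' differences between realized per-type event rates (averaged over `m`
#' cohorts of `n`, common random numbers across candidates) and the targets:
#' a coarse grid pass followed by a fine pass around the coarse minimizer.
#'
#' @inheritParams realized_event_rates
#' @param interval search interval for `C`.
#' @param coarse,fine grid steps of the two passes.
#' @param m_coarse cohorts per candidate in the coarse pass.
#' @return List of class `wce_rate_calibration` with `value`, `realized`
#'   (rates at the minimizer), `targets`, `objective` (fine-pass grid), and
#'   `boundary` flag. A minimizer on the interval boundary triggers a
#'   warning.
#' @export
calibrate_rate_coefficient <- function(config, arm = "treatment",
                                       interval = c(1, 5), m = 200, n = 1500,
                                       coarse = 0.1, fine = 0.01,
                                       m_coarse = max(20, m %/% 10),
                                       seed = NULL) {
  stopifnot(inherits(config, "wce_trial_config"))
  targets <- config$rates[[arm]]
  cfg <- config
  if (is.na(cfg$no_event_mean[[arm]])) {
    b <- no_event_bounds(cfg, arm)
    cfg$no_event_mean[[arm]] <- mean(b)  # analytic midpoint as a prior
  }
  eval_C <- function(C, mm, s) {
    cfg$rate_coefficient[[arm]] <- C
    rr <- realized_event_rates(cfg, arm, m = mm, n = n, seed = s)
    sum((rr - targets)^2)
  }
  s1 <- if (!is.null(seed)) seed else NULL
  g1 <- seq(interval[1], interval[2], by = coarse)
  o1 <- vapply(g1, eval_C, 0, mm = m_coarse, s = s1)
  c1 <- g1[which.min(o1)]
  g2 <- seq(max(interval[1], c1 - 1.5 * coarse),
            min(interval[2], c1 + 1.5 * coarse), by = fine)
  s2 <- if (!is.null(seed)) seed + 1L else NULL
  o2 <- vapply(g2, eval_C, 0, mm = m, s = s2)
  C <- g2[which.min(o2)]
  boundary <- C <= interval[1] + fine / 2 || C >= interval[2] - fine / 2
  if (boundary)
    warning("rate-coefficient minimizer lies on the search-interval boundary; the simulation model may be mis-specified")
  cfg$rate_coefficient[[arm]] <- C
  realized <- realized_event_rates(cfg, arm, m = m, n = n,
                                   seed = if (!is.null(seed)) seed + 2L)
  structure(list(value = C, realized = realized, targets = targets,
                 objective = data.frame(C = g2, sse = o2),
                 boundary = boundary, arm = arm,
                 no_event_mean = cfg$no_event_mean[[arm]]),
            class = "wce_rate_calibration")
}

#' @export
print.wce_rate_calibration <- function(x, ...) {
  cat(sprintf("Calibrated incident-rate coefficient (arm %s): C = %.2f\n",
              x$arm, x$value))
  print(rbind(target = x$targets, realized = round(unclass(x$realized), 4)))
  invisible(x)
}

#' Calibrate all arms of a simulation config
#'
#' For each arm: seed the no-event mean at the analytic-bounds midpoint,
#' calibrate `C` against the target rates, re-run the no-event fixed point at
#' that `C`, and refine `C` once at the converged mean. Returns the config
#' with `no_event_mean` and `rate_coefficient` filled in.
#'
#' @inheritParams calibrate_rate_coefficient
#' @param arms arms to calibrate (default all).
#' @return The calibrated `wce_trial_config`, with the per-arm calibration
#'   objects in attribute `calibration`.
#' @export
calibrate_config <- function(config, arms = config$arms, m = 200, n = 1500,
                             seed = NULL, tol = 0.05) {
  detail <- list()
  for (a in arms) {
    rc <- calibrate_rate_coefficient(config, a, m = m, n = n,
                                     seed = if (!is.null(seed)) derive_seed(seed, 1))
    config$rate_coefficient[[a]] <- rc$value
    fp <- calibrate_no_event_mean(config, a, m = m, n = n, tol = tol,
                                  seed = if (!is.null(seed)) derive_seed(seed, 2))
    config$no_event_mean[[a]] <- fp$value
    rc2 <- calibrate_rate_coefficient(config, a, m = m, n = n,
                                      seed = if (!is.null(seed)) derive_seed(seed, 3))
    config$rate_coefficient[[a]] <- rc2$value
    detail[[a]] <- list(no_event = fp, rate = rc2)
  }
  attr(config, "calibration") <- detail
  config
}
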