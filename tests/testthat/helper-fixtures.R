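# shared fixtures, all built in code

mace <- mace_catalog()

make_trial <- function(..., catalog = mace, followup = 30) {
  rows <- list(...)
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(subject_id = r[[1]], arm = r[[2]], time = as.numeric(r[[3]]),
               event_type = r[[4]], stringsAsFactors = FALSE)))
  wce_trial(tab, catalog, followup)
}

fixture25 <- function() {
  read_trial_table(system.file("extdata", "synthetic_trial_25.csv",
                               package = "wcesurv"),
                   mace, followup = 30)
}

# a random small single-arm trial for property loops
random_trial <- function(n = 40, seed = 1, followup = 30) {
  cfg <- trial_config(
    rates = list(a = c(REMI = 0.25, CHF = 0.2, SHK = 0.15, DTH = 0.12)),
    n = n,
    no_event_mean = c(a = 10), rate_coefficient = c(a = 1.6))
  simulate_trial(cfg, seed = seed, n = n)
}

# Table-1 study conditions with calibrated constants, computed once per run
calibrated_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- trial_config()
      for (a in cfg$arms) {
        rc <- calibrate_rate_coefficient(cfg, a, m = 60, n = 1500,
                                         seed = 424201)
        cfg$rate_coefficient[[a]] <- rc$value
        fp <- calibrate_no_event_mean(cfg, a, m = 120, n = 1500, seed = 424202)
        cfg$no_event_mean[[a]] <- fp$value
      }
      cache <<- cfg
    }
    cache
  }
})

# unweighted Kaplan-Meier oracle on first-event times (no censoring before
# followup); returns survival at the requested times
km_oracle <- function(trial, arm, times) {
  ids <- trial_subjects(trial)[[arm]]
  evrows <- trial$arm == arm & trial$event_type != "NONE"
  first <- tapply(trial$time[evrows], trial$subject_id[evrows], min)
  tt <- rep(attr(trial, "followup"), length(ids))
  st <- rep(0, length(ids))
  tt[match(names(first), ids)] <- first
  st[match(names(first), ids)] <- 1
  km <- survival::survfit(survival::Surv(tt, st) ~ 1)
  summary(km, times = times)$surv
}
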