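test_that("config validation enforces the simulation contract", {
  expect_error(trial_config(rates = list(a = c(0.5, 0.4, 0.2, 0.1))), "sum")
  expect_error(trial_config(rates = list(c(0.1, 0.1, 0.1, 0.1))), "named")
  expect_error(trial_config(rates = list(a = c(0.1, 0.1, 0.1))), "one per")
  expect_error(trial_config(mean_times = c(3, 2.4, -1, 5.5)), "positive")
  expect_error(trial_config(rate_coefficient = c(treatment = 0.5)), ">= 1")
  cfg <- trial_config(rate_coefficient = c(treatment = 40))
  expect_error(draw_subjects(cfg, "control"), "not calibrated")
})

test_that("degenerate configs behave as advertised", {
  # all rates zero: every subject event-free for the whole follow-up
  cfg <- trial_config(rates = list(a = c(REMI = 0, CHF = 0, SHK = 0, DTH = 0)),
                      n = 50, no_event_mean = c(a = 16),
                      rate_coefficient = c(a = 1))
  tr <- simulate_trial(cfg, seed = 1)
  expect_true(all(tr$event_type == "NONE"))
  expect_equal(length(unique(tr$subject_id)), 50)

  # near-certain immediate death: single terminal event per subject whose
  # mean time matches the truncated-exponential mean
  cfg <- trial_config(rates = list(a = c(REMI = 0, CHF = 0, SHK = 0, DTH = 0.999)),
                      no_event_mean = c(a = 16), rate_coefficient = c(a = 1))
  s <- draw_subjects(cfg, "a", n = 10000, seed = 2)
  expect_true(all(s$events$event_type == "DTH"))
  expect_lte(max(table(s$events$i)), 1)
  mu <- 5.5; tau <- 30
  m_trunc <- (mu - (tau + mu) * exp(-tau / mu)) / (1 - exp(-tau / mu))
  expect_lt(abs(mean(s$events$time) - m_trunc),
            3 * sd(s$events$time) / sqrt(nrow(s$events)))
})

test_that("simulated histories respect follow-up and the terminal contract", {
  trl <- simulate_trial(calibrated_config(), seed = 77, n = 1200)
  tau <- attr(trl, "followup")
  expect_true(all(trl$time > 0 & trl$time <= tau))
  # wce_trial() validation passed, so no events after death; check sojourns
  ev <- trl[trl$event_type != "NONE", ]
  gaps <- unlist(tapply(ev$time, ev$subject_id, diff))
  expect_true(all(gaps > 0 | abs(gaps) < 1e-9))
  # realized death rates within 3 binomial SEs of targets
  cfg <- calibrated_config()
  for (arm in c("treatment", "control")) {
    target <- cfg$rates[[arm]][["DTH"]]
    died <- sum(ev$event_type == "DTH" & ev$arm == arm)
    se <- sqrt(target * (1 - target) / 1200)
    expect_lt(abs(died / 1200 - target), 3 * se)
  }
})

test_that("simulation is reproducible and symmetric in arm labels", {
  cfg <- calibrated_config()
  t1 <- simulate_trial(cfg, seed = 5, n = 200)
  t2 <- simulate_trial(cfg, seed = 5, n = 200)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_trial(cfg, seed = 6, n = 200)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))

  # swapping the arm labels (keeping each arm's parameters) swaps the outputs
  swapped <- cfg
  for (f in c("rates", "no_event_mean", "rate_coefficient"))
    names(swapped[[f]]) <- c("control", "treatment")
  swapped$arms <- c("control", "treatment")
  t4 <- simulate_trial(swapped, seed = 5, n = 200)
  a <- as.data.frame(t1); b <- as.data.frame(t4)
  relabel <- function(d) {
    d$arm <- ifelse(d$arm == "treatment", "control", "treatment")
    d$subject_id <- sub("^treatment", "TMP", d$subject_id)
    d$subject_id <- sub("^control", "treatment", d$subject_id)
    d$subject_id <- sub("^TMP", "control", d$subject_id)
    d <- d[order(d$arm, d$subject_id, d$time, d$event_type), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(relabel(a), b, ignore_attr = TRUE)
})

test_that("no-event sojourn bounds follow the accounting identity", {
  cfg <- trial_config()
  b <- no_event_bounds(cfg, "treatment")
  expect_equal(unname(b), c(15.9, 16.8), ignore_attr = TRUE)
  expect_equal(unname(attr(b, "after_death_extremes")), c(0, 0.9))
  # control arm: 6% death rate moves only the lower bound
  expect_equal(unname(no_event_bounds(cfg, "control")), c(15.0, 16.8),
               ignore_attr = TRUE)
  # zero death rate collapses the bounds
  cfg0 <- trial_config(rates = list(a = c(REMI = 0.06, CHF = 0.05,
                                          SHK = 0.04, DTH = 0)))
  b0 <- no_event_bounds(cfg0, "a")
  expect_equal(b0[["lower"]], b0[["upper"]])
  # infeasible mean times are refused
  cfg_bad <- trial_config(mean_times = c(10, 10, 10, 5.5))
  expect_error(no_event_bounds(cfg_bad, "treatment"), "exceed")
})

test_that("the no-event fixed point converges into its bounds", {
  # zero death rate: converges immediately to the degenerate bound
  cfg0 <- trial_config(rates = list(a = c(REMI = 0.06, CHF = 0.05,
                                          SHK = 0.04, DTH = 0)),
                       rate_coefficient = c(a = 2.5))
  fp0 <- calibrate_no_event_mean(cfg0, "a", m = 5, n = 500, seed = 1)
  expect_equal(fp0$value, no_event_bounds(cfg0, "a")[["upper"]])
  expect_equal(fp0$iterations, 2)

  # study conditions, scaled-down m: lands in [15.9, 16.8], later iterates too
  cfg <- trial_config(rate_coefficient = c(treatment =
    calibrated_config()$rate_coefficient[["treatment"]]))
  fp <- calibrate_no_event_mean(cfg, "treatment", m = 100, n = 1500,
                                start = 1, seed = 2)
  expect_true(fp$converged)
  expect_gte(fp$value, 15.9)
  expect_lte(fp$value, 16.8)
  expect_true(all(fp$trace[-(1:2)] >= 15.9 & fp$trace[-(1:2)] <= 16.8))
})

test_that("realized event rates fall as the incident-rate coefficient grows", {
  cfg <- trial_config(no_event_mean = c(treatment = 16.35))
  totals <- vapply(c(1, 2, 3, 4, 5), function(C) {
    cfg$rate_coefficient[["treatment"]] <- C
    sum(realized_event_rates(cfg, "treatment", m = 30, n = 1500, seed = 9))
  }, 0)
  expect_true(all(diff(totals) < 0))
})

test_that("calibrated rates converge to their targets (law of large numbers)", {
  cfg <- calibrated_config()
  rr <- realized_event_rates(cfg, "treatment", m = 100, n = 1500, seed = 31)
  target <- cfg$rates$treatment
  se <- sqrt(target * (1 - target) / (100 * 1500))
  # a small calibration residual remains; allow it on top of MC noise
  expect_true(all(abs(rr - target) < 0.0025 + 3 * se))
})

test_that("event types are drawn independently; realized counts are near-uncorrelated", {
  # the draws are independent by construction; realized per-subject counts
  # share the 30-day budget and the death stopping rule, which leaves a
  # small residual correlation — weak, not zero
  cfg <- calibrated_config()
  s <- draw_subjects(cfg, "treatment", n = 50000, seed = 41)
  cnt <- matrix(0, 50000, 4)
  for (k in 1:4) {
    tb <- table(s$events$i[s$events$event_type == mace$event_type[k]])
    cnt[as.integer(names(tb)), k] <- tb
  }
  cc <- cor(cnt)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("config YAML round-trips", {
  cfg <- calibrated_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_config(cfg, path)
  back <- read_trial_config(path)
  expect_equal(back$rates, cfg$rates)
  expect_equal(back$mean_times, cfg$mean_times)
  expect_equal(back$no_event_mean, cfg$no_event_mean, tolerance = 1e-6)
  expect_equal(back$rate_coefficient, cfg$rate_coefficient, tolerance = 1e-6)
})
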