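test_that("subject paths multiply (1 - w) factors in event order", {
  tr <- make_trial(
    list("i1", "a", 3, "SHK"), list("i1", "a", 8, "CHF"),     # 0.5 then 0.35
    list("i2", "a", 30, "NONE"),                              # constant 1
    list("i3", "a", 5, "DTH"),                                # drops to 0
    list("i4", "a", 2, "REMI"), list("i4", "a", 9, "REMI"),
    list("i4", "a", 20, "CHF"))                               # 0.8, 0.64, 0.448
  p <- subject_paths(tr)
  ridx <- match(c("i1", "i2", "i3", "i4"), p$subject_id)
  at <- function(i, t) p$S[ridx[i], match(t, p$grid)]
  expect_equal(at(1, 3), 0.5)
  expect_equal(at(1, 8), 0.35)
  expect_equal(p$S[ridx[2], ], rep(1, length(p$grid)))
  expect_equal(at(3, 3), 1)       # right-continuous: 1 before death
  expect_equal(at(3, 5), 0)       # exactly 0 at and after the terminal event
  expect_equal(at(3, 20), 0)
  expect_equal(unname(p$S[ridx[4], match(c(2, 9, 20), p$grid)]),
               c(0.8, 0.64, 0.448))
  # log-sum cross-check of the product
  expect_equal(at(4, 20), exp(log(0.8) + log(0.8) + log(0.7)))
  # paths are monotone non-increasing within [0, 1]
  expect_true(all(p$S >= 0 & p$S <= 1))
  expect_true(all(p$S[, -1] - p$S[, -ncol(p$S)] <= 1e-15))
})

test_that("simultaneous same-subject events multiply within a single step", {
  tr <- make_trial(list("s", "a", 4, "REMI"), list("s", "a", 4, "SHK"),
                   list("t", "a", 30, "NONE"))
  p <- subject_paths(tr)
  expect_equal(p$grid, 4)
  expect_equal(p$S[match("s", p$subject_id), 1], 0.8 * 0.5)
})

test_that("pooled curve is the mean of subject paths and obeys the product recursion", {
  # n = 2: one event-free subject, one death at day 5
  tr2 <- make_trial(list("x", "a", 5, "DTH"), list("y", "a", 30, "NONE"))
  cv <- wce_fit(tr2)$curves$a
  expect_equal(cv$estimate, c(1, 0.5))
  expect_equal(cv$time, c(0, 5))

  for (case in list(fixture25(), random_trial(60, seed = 7),
                    random_trial(35, seed = 8))) {
    for (arm in unique(case$arm)) {
      p <- subject_paths(case, arm)
      cv <- wce_fit(case)$curves[[arm]]
      # mean form at every grid point
      expect_equal(cv$estimate[-1], unname(colMeans(p$S)), tolerance = 1e-13)
      # product-limit form from the heuristic d_j / n_j increments
      inc <- heuristic_increments(case, arm)
      expect_lt(max(abs(cumprod(1 - inc$hazard) - cv$estimate[-1])), 1e-12)
      # curve invariants
      expect_equal(cv$estimate[1], 1)
      expect_true(all(diff(cv$estimate) <= 1e-15))
      expect_true(all(cv$estimate >= 0 & cv$estimate <= 1))
    }
  }
})

test_that("heuristic increments generalize the Kaplan-Meier counts", {
  # all subjects event-free: d identically 0
  allfree <- make_trial(list("a1", "a", 30, "NONE"), list("a2", "a", 30, "NONE"))
  expect_equal(nrow(heuristic_increments(allfree)), 0)
  expect_equal(wce_fit(allfree)$curves$a$estimate, 1)

  # one death among 10: d = 1, n = 10, hazard 0.1
  rows <- c(list(list("d1", "a", 5, "DTH")),
            lapply(2:10, function(i) list(paste0("d", i), "a", 30, "NONE")))
  tr <- do.call(make_trial, rows)
  inc <- heuristic_increments(tr)
  expect_equal(inc$d, 1)
  expect_equal(inc$n_risk, 10)
  expect_equal(inc$hazard, 0.1)

  # weights-1 first-event data: (d_j, n_j) equal the KM death/risk-set counts
  trl <- random_trial(80, seed = 11)
  ev <- trl[trl$event_type != "NONE", ]
  first <- ev[!duplicated(ev$subject_id), ]
  first$event_type <- "DTH"
  roster <- trl[trl$event_type == "NONE", ]
  tr1 <- wce_trial(rbind(first, roster), mace, 30)
  inc <- heuristic_increments(tr1)
  km <- survival::survfit(survival::Surv(
    c(first$time, rep(30, nrow(roster))),
    c(rep(1, nrow(first)), rep(0, nrow(roster)))) ~ 1)
  at <- match(inc$time, km$time)
  expect_equal(inc$d, km$n.event[at])
  expect_equal(inc$n_risk, km$n.risk[at])
})

test_that("traditional analysis is the weights-1 first-event special case", {
  # a non-fatal first event counts as a full composite event
  tr <- make_trial(list("p", "a", 3, "SHK"), list("p", "a", 8, "DTH"),
                   list("q", "a", 30, "NONE"))
  cv <- traditional_fit(tr)$curves$a
  expect_equal(cv$time, c(0, 3))        # day-8 death never enters
  expect_equal(cv$estimate, c(1, 0.5))

  # event-free cohort stays at 1
  allfree <- make_trial(list("a1", "a", 30, "NONE"), list("a2", "a", 30, "NONE"))
  expect_equal(traditional_fit(allfree)$curves$a$estimate, 1)

  # matches the independent Kaplan-Meier oracle exactly (no censoring)
  trl <- simulate_trial(calibrated_config(), seed = 301, n = 1500)
  for (arm in c("treatment", "control")) {
    cv <- traditional_fit(trl)$curves[[arm]]
    expect_lt(max(abs(km_oracle(trl, arm, cv$time[-1]) - cv$estimate[-1])),
              1e-12)
  }
})

test_that("explicit weights-1 truncated data makes the weighted fit equal the traditional fit", {
  trl <- random_trial(70, seed = 13)
  ev <- trl[trl$event_type != "NONE", ]
  first <- ev[!duplicated(ev$subject_id), ]
  first$event_type <- "DTH"   # weight 1 in the catalog
  tr1 <- wce_trial(rbind(first, trl[trl$event_type == "NONE", ]), mace, 30)
  fw <- wce_fit(tr1)$curves$a
  ft <- traditional_fit(trl)$curves$a
  expect_identical(fw$time, ft$time)
  expect_equal(fw$estimate, ft$estimate)
  expect_equal(fw$variance, ft$variance)
})

test_that("weighted survival dominates the traditional estimate pointwise", {
  trl <- simulate_trial(calibrated_config(), seed = 302, n = 800)
  for (arm in c("treatment", "control")) {
    fw <- wce_fit(trl)$curves[[arm]]
    ft <- traditional_fit(trl)$curves[[arm]]
    # evaluate the traditional step function on the weighted grid
    st <- stepfun(ft$time[-1], ft$estimate)
    expect_true(all(fw$estimate - st(fw$time) >= -1e-12))
  }
})

test_that("subject order never changes any output", {
  trl <- fixture25()
  perm <- as.data.frame(trl)[sample(nrow(trl)), ]
  trp <- wce_trial(perm, mace, 30)
  f1 <- wce_fit(trl)
  f2 <- wce_fit(trp)
  expect_equal(f1$curves, f2$curves)
})

test_that("empty input and missing arms error cleanly", {
  expect_error(wce_trial(data.frame(), mace, 30), "columns|empty")
  tr <- fixture25()
  expect_error(subject_paths(tr, "placebo"), "no arm")
  expect_error(subject_paths(tr), "specify")
})
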