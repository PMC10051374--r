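# Caliper volumetry, eligibility, outcome classification, Kaplan-Meier.

test_that("ellipsoidal volume formula and its scaling properties", {
  expect_equal(tumor_volume(10, 10), 500)
  expect_equal(tumor_volume(12, 8), 384)
  expect_equal(tumor_volume(7, 0), 0)
  expect_error(tumor_volume(8, 12), class = "pttdose_error")
  # cubic scaling and monotonicity in each axis
  expect_equal(tumor_volume(2 * 10, 2 * 8), 8 * tumor_volume(10, 8))
  expect_gt(tumor_volume(11, 8), tumor_volume(10, 8))
  expect_gt(tumor_volume(10, 9), tumor_volume(10, 8))
})

test_that("eligibility window is inclusive on both ends", {
  expect_true(is_eligible(100))
  expect_false(is_eligible(49.9))
  expect_true(is_eligible(50))
  expect_true(is_eligible(150))
  expect_false(is_eligible(150.1))
  expect_error(is_eligible(100, low = 150, high = 50),
               class = "pttdose_error")
})

test_that("declining-to-zero trajectories classify as complete regression", {
  rec <- record_from_volumes("a", "GF", days = seq(0, 120, by = 5),
                             volumes = pmax(0, 100 - 30 * seq(0, 24)))
  expect_equal(classify_outcome(rec)$label, "complete_regression")
  # appending more sub-threshold measurements does not change the label
  rec2 <- record_from_volumes("a", "GF", days = c(seq(0, 120, by = 5), 125),
                              volumes = c(pmax(0, 100 - 30 * seq(0, 24)), 0),
                              followup_end = 125)
  expect_equal(classify_outcome(rec2)$label, "complete_regression")
  # label is invariant to rescaling of the measurement days
  rec3 <- record_from_volumes("a", "GF", days = 2 * seq(0, 120, by = 5),
                              volumes = pmax(0, 100 - 30 * seq(0, 24)),
                              followup_end = 240)
  expect_equal(classify_outcome(rec3)$label, "complete_regression")
})

test_that("growing trajectories classify as progression", {
  rec <- record_from_volumes("gm", "GM", days = seq(0, 45, by = 5),
                             volumes = 100 * exp(0.12 * seq(0, 45, by = 5)),
                             event = "sacrifice", event_day = 45)
  expect_equal(classify_outcome(rec)$label, "progression")
})

test_that("regression followed by sustained regrowth is recurrence", {
  v <- c(100, 40, 2, 1, 1, 20, 60, 150)
  rec <- record_from_volumes("r", "GF", days = seq_along(v) * 5 - 5,
                             volumes = v)
  expect_equal(classify_outcome(rec)$label, "recurrence")
})

test_that("early deaths without trajectory are non-evaluable", {
  rec <- event_only_record("gf2e", "GF", event = "death", event_day = 10)
  expect_equal(classify_outcome(rec)$label, "non_evaluable")
  none <- event_only_record("x", "GF")
  expect_error(classify_outcome(none), class = "pttdose_error")
})

test_that("paper-style cohort bookkeeping: 11 regressions of 12 evaluable", {
  regress <- lapply(1:11, function(i) {
    record_from_volumes(paste0("r", i), "PTT", days = seq(0, 120, by = 10),
                        volumes = pmax(0, 100 * exp(-0.3 * seq(0, 120, by = 10))))
  })
  prog <- record_from_volumes("gm-sm", "GM", days = seq(0, 45, by = 5),
                              volumes = 80 * exp(0.1 * seq(0, 45, by = 5)),
                              event = "sacrifice", event_day = 45)
  labels <- vapply(c(regress, list(prog)),
                   function(r) classify_outcome(r)$label, character(1))
  expect_equal(sum(labels == "complete_regression"), 11)
  expect_equal(sum(labels == "progression"), 1)
})

test_that("product-limit survival matches direct counting", {
  # no events: survival 1 everywhere
  alive <- lapply(1:5, function(i) event_only_record(paste0("a", i)))
  expect_equal(km_survival(alive)$surv_at_horizon, 1)
  expect_equal(km_survival(alive)$surv_pct, 100)

  # single animal with an event on day 1
  one <- list(event_only_record("z", event = "death", event_day = 1))
  expect_equal(km_survival(one)$surv_at_horizon, 0)

  # 13 animals, 2 events, no censoring before the horizon
  cohort <- c(list(event_only_record("d", event = "death", event_day = 10),
                   event_only_record("s", event = "sacrifice",
                                     event_day = 45)),
              lapply(1:11, function(i) event_only_record(paste0("c", i))))
  km <- km_survival(cohort, horizon = 120)
  expect_equal(km$surv_at_horizon, 11 / 13, tolerance = 1e-12)
  expect_equal(km$surv_pct, 85)

  # with no censoring the curve equals the empirical survivor fraction
  set.seed(4)
  days <- sample(1:119, 8)
  all_events <- lapply(seq_along(days), function(i) {
    event_only_record(paste0("e", i), event = "death", event_day = days[i])
  })
  km2 <- km_survival(all_events, horizon = 120)
  for (k in seq_len(nrow(km2$curve))) {
    t_k <- km2$curve$time[k]
    expect_equal(km2$curve$surv[k], mean(days > t_k), tolerance = 1e-12)
  }

  expect_error(km_survival(cohort, horizon = 5), class = "pttdose_error")
})
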