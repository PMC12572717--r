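test_that("gap adjustment grants carry-over and conserves supply", {
  # abutting fills merge into one interval
  expect_equal(gap_adjust(c(0, 30), c(30, 30)),
               data.frame(start_day = 0L, end_day = 60L))
  # early refill is pushed forward to the previous supply's end
  expect_equal(gap_adjust(c(0, 20), c(30, 30)),
               data.frame(start_day = 0L, end_day = 60L))
  # a true gap yields two intervals
  iv <- gap_adjust(c(0, 50), c(30, 30))
  expect_equal(iv$start_day, c(0L, 50L))
  expect_equal(iv$end_day, c(30L, 80L))
  # supply conservation on random histories
  set.seed(101)
  for (r in 1:20) {
    h <- random_history(15)
    iv <- gap_adjust(h$day, h$supply)
    expect_equal(sum(iv$end_day - iv$start_day), sum(h$supply))
    expect_true(all(diff(iv$start_day) > 0))
    expect_true(all(iv$end_day > iv$start_day))
    expect_true(all(iv$start_day[-1] > iv$end_day[-nrow(iv)]))
  }
})

test_that("gap adjustment rejects invalid input", {
  expect_error(gap_adjust(c(10, 0), c(30, 30)), "sorted")
  expect_error(gap_adjust(0, 0), "days_supplied")
  expect_error(gap_adjust(0, -5), "days_supplied")
  expect_error(gap_adjust(integer(0), integer(0)), "empty")
})

test_that("windowed coverage matches exhaustive day enumeration", {
  iv <- gap_adjust(0, 360)
  expect_equal(unname(window_coverage(iv, NULL, 2)), c(90L, 0L))
  # hospital credit on an otherwise uncovered window
  stays <- data.frame(admit_day = 0L, discharge_day = 9L)
  expect_equal(unname(window_coverage(NULL, stays, 1)), c(0L, 10L))
  # pre-index stay days are clipped, not rejected
  stays2 <- data.frame(admit_day = -5L, discharge_day = 4L)
  expect_equal(unname(window_coverage(NULL, stays2, 1)), c(0L, 5L))
  # randomized intervals + stays vs brute-force day sets
  set.seed(202)
  for (r in 1:30) {
    h <- random_history(8, horizon = 360)
    iv <- gap_adjust(h$day, h$supply)
    cov_vec <- logical(360)
    for (i in seq_len(nrow(iv))) {
      d <- iv$start_day[i]:(iv$end_day[i] - 1)
      cov_vec[d[d < 360] + 1] <- TRUE
    }
    ad <- sample(0:300, 2)
    stays <- data.frame(admit_day = ad, discharge_day = ad + sample(3:20, 2))
    stay_days <- unlist(lapply(seq_len(2), function(i)
      stays$admit_day[i]:stays$discharge_day[i]))
    for (k in 1:4) {
      got <- window_coverage(iv, stays, k)
      expect_equal(unname(got), window_days_oracle(cov_vec, stay_days, k))
    }
  }
})

test_that("hospital credit modes differ only on overlap days", {
  iv <- gap_adjust(0, 30)                      # covers days 0..29
  stays <- data.frame(admit_day = 20L, discharge_day = 39L)
  expect_equal(unname(window_coverage(iv, stays, 1, mode = "union")),
               c(30L, 10L))
  expect_equal(unname(window_coverage(iv, stays, 1, mode = "sum")),
               c(30L, 20L))
})

test_that("PDC formula caps at 1 and rejects bad input", {
  expect_equal(compute_pdc(90, 0), 1)
  expect_equal(compute_pdc(85, 5), 1)
  expect_equal(compute_pdc(85, 20), 1)    # cap active
  expect_equal(compute_pdc(8, 0), 8 / 90)
  expect_error(compute_pdc(-1, 0), "non-negative")
  expect_error(compute_pdc(0, 91), "exceed")
})

test_that("PDC-to-state mapping is the left-closed decile binning", {
  expect_equal(map_pdc_to_state(0.95), 10L)
  expect_equal(map_pdc_to_state(0), 1L)
  expect_equal(map_pdc_to_state(8 / 90), 1L)     # 8.9% -> state 1
  expect_equal(map_pdc_to_state(9 / 90), 2L)     # 10.0% -> state 2
  expect_equal(map_pdc_to_state(0.10), 2L)
  expect_error(map_pdc_to_state(1.2), "0, 1")
  # every state attainable from an integer day count
  days <- 0:90
  states <- map_pdc_to_state(compute_pdc(days, 0))
  expect_setequal(unique(states), 1:10)
  # non-decreasing step function
  grid <- seq(0, 1, by = 1e-3)
  expect_true(all(diff(map_pdc_to_state(grid)) >= 0))
  # bin boundaries at exact day counts: state s starts at 9(s-1) days
  expect_equal(map_pdc_to_state(compute_pdc(c(9, 18, 27, 72, 80, 81), 0)),
               c(2L, 3L, 4L, 9L, 9L, 10L))
})

test_that("cohort windows: eligibility, determinism, orchestration", {
  base <- data.frame(patient_id = c("a", "b"),
                     index_date = as.Date("2015-01-01"),
                     age = c(70, 80), chads_vasc = c(4, 5))
  # patient a: continuous 1800-day coverage; patient b: one fill only
  disp <- data.frame(
    patient_id = c(rep("a", 20), "b"),
    dispense_date = as.Date("2015-01-01") + c(90 * (0:19), 0),
    drug_code = "apixaban",
    days_supplied = c(rep(90L, 20), 30L)
  )
  w <- suppressMessages(build_cohort_windows(disp, NULL, base))
  expect_equal(nrow(w), 20L)                     # b excluded by eligibility
  expect_equal(unique(w$patient_id), "a")
  expect_true(all(w$state == 10L))
  expect_true(all(w$covered_days == 90L))
  # permuting fill order changes nothing (fills are sorted internally)
  disp2 <- disp[sample(nrow(disp)), ]
  w2 <- suppressMessages(build_cohort_windows(disp2, NULL, base))
  expect_identical(w, w2)
  # patient without a baseline row is dropped with a message
  disp3 <- rbind(disp, data.frame(patient_id = "ghost",
                                  dispense_date = as.Date("2015-01-01"),
                                  drug_code = "apixaban",
                                  days_supplied = 90L))
  expect_message(build_cohort_windows(disp3, NULL, base), "baseline")
})

test_that("day conservation holds across windows for random histories", {
  set.seed(303)
  n_windows <- 8
  for (r in 1:50) {
    h <- random_history(12, horizon = 90 * n_windows)
    iv <- gap_adjust(h$day, h$supply)
    per_window <- vapply(seq_len(n_windows), function(k)
      window_coverage(iv, NULL, k)[1], integer(1))
    lo <- pmax(iv$start_day, 0)
    hi <- pmin(iv$end_day, 90 * n_windows)
    expect_equal(sum(per_window), sum(pmax(hi - lo, 0)))
  }
})
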