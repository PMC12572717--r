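test_that("expected state is the probability-weighted state index", {
  p <- rep(0, 10); p[10] <- 1
  expect_equal(expected_state(p), 10)
  p2 <- rep(0, 10); p2[9:10] <- 0.5
  expect_equal(expected_state(p2), 9.5)
  expect_error(expected_state(rep(0.2, 10)), "sum to 1")
  set.seed(91)
  for (r in 1:20) {
    v <- runif(10); v <- v / sum(v)
    expect_equal(expected_state(v), sum((1:10) * v), tolerance = 1e-12)
  }
})

make_sop_list <- function(n, seed = 1, windows = 5:20) {
  # synthetic per-subject SOP matrices with controlled spread
  set.seed(seed)
  out <- list()
  for (i in seq_len(n)) {
    m <- matrix(runif(length(windows) * 10), length(windows), 10)
    m <- m / rowSums(m)
    out[[sprintf("S%03d", i)]] <-
      structure(m, class = c("sop_matrix", "matrix"), windows = windows,
                initial_state = 10L,
                dimnames = list(windows, paste0("state", 1:10)))
  }
  out
}

test_that("subject calibration groups deciles deterministically", {
  sl <- make_sop_list(50, seed = 2)
  obs <- do.call(rbind, lapply(names(sl), function(id)
    data.frame(patient_id = id, window_index = 5:20,
               state = sample(1:10, 16, replace = TRUE))))
  pred <- pdcmarkov:::sop_prediction_table(sl, obs)
  cal <- subject_calibration(pred)
  expect_equal(nrow(cal), 10L)
  expect_true(all(abs(cal$n - 5) <= 1))          # decile sizes differ by <= 1
  expect_equal(sum(cal$n), 50L)
  # identical predictions: single occupied group equals the overall mean
  pred2 <- pred
  pred2$expected <- 5
  cal2 <- subject_calibration(pred2)
  expect_equal(weighted.mean(cal2$mean_observed, cal2$n),
               mean(tapply(pred2$observed, pred2$patient_id, mean)))
  # ordering of subjects does not change the table
  cal3 <- subject_calibration(pred[rev(seq_len(nrow(pred))), ])
  expect_equal(cal3, cal)
  # stratified variant covers the early/middle/late split
  cs <- subject_calibration(pred, strata = "default")
  expect_setequal(unique(cs$stratum), c("early", "middle", "late"))
})

test_that("GAM smoother recovers exact and linear relations", {
  x <- seq(1, 10, length.out = 300)
  out <- smoothed_calibration(data.frame(expected = x, observed = x))
  expect_lt(max(abs(out$smoothed - out$predicted)), 1e-6)
  set.seed(93)
  y <- 2 + 0.8 * x
  out2 <- smoothed_calibration(data.frame(expected = x, observed = y))
  slope <- coef(lm(smoothed ~ predicted, data = out2))[2]
  expect_equal(unname(slope), 0.8, tolerance = 1e-3)
  # degenerate constant predictions give a flat line
  out3 <- smoothed_calibration(data.frame(expected = rep(5, 60),
                                          observed = rnorm(60, 3)))
  expect_equal(var(out3$smoothed), 0)
})

test_that("SOP width uses the linear-interpolation IQR convention", {
  # identical subjects: all widths zero
  sl <- make_sop_list(1, seed = 3)
  sl10 <- setNames(rep(sl, 10), sprintf("S%03d", 1:10))
  w <- sop_width(sl10)
  expect_true(all(w$by_window$width == 0))
  expect_true(all(w$average == 0))
  # 50/50 split between SOP(10) = 0.2 and 0.6: brute-force quantile oracle
  mk <- function(p10) {
    m <- matrix((1 - p10) / 9, 16, 10)
    m[, 10] <- p10
    structure(m, class = c("sop_matrix", "matrix"), windows = 5:20,
              initial_state = 10L,
              dimnames = list(5:20, paste0("state", 1:10)))
  }
  sl2 <- setNames(c(rep(list(mk(0.2)), 4), rep(list(mk(0.6)), 4)),
                  sprintf("S%03d", 1:8))
  w2 <- sop_width(sl2)
  vals <- c(rep(0.2, 4), rep(0.6, 4))
  expect_equal(unname(w2$average["state10"]),
               quantile_oracle(vals, 0.75) - quantile_oracle(vals, 0.25),
               tolerance = 1e-12)
  # subject order invariance
  w3 <- sop_width(rev(sl2))
  expect_equal(w3$average, w2$average)
})

test_that("bootstrap width envelopes are reproducible and degenerate safely", {
  sl <- make_sop_list(30, seed = 4)
  b1 <- bootstrap_widths(sl, reps = 50, seed = 11)
  b2 <- bootstrap_widths(sl, reps = 50, seed = 11)
  expect_identical(b1, b2)
  expect_true(all(b1$average$lower <= b1$average$median + 1e-12))
  expect_true(all(b1$average$upper >= b1$average$median - 1e-12))
  expect_error(bootstrap_widths(sl, reps = 0), "reps")
  # identical subjects collapse the envelope to zero
  sl1 <- make_sop_list(1, seed = 5)
  slid <- setNames(rep(sl1, 8), sprintf("S%03d", 1:8))
  b3 <- bootstrap_widths(slid, reps = 20, seed = 1)
  expect_true(all(b3$average$median == 0 & b3$average$upper == 0))
})

test_that("mean-time absolute error summarizes subject-level discrepancy", {
  windows <- 5:20
  mk_point <- function(states) {
    m <- matrix(0, 16, 10)
    m[cbind(1:16, states)] <- 1
    structure(m, class = c("sop_matrix", "matrix"), windows = windows,
              initial_state = 10L,
              dimnames = list(windows, paste0("state", 1:10)))
  }
  states <- sample(c(9, 10), 16, replace = TRUE)
  sl <- list(A = mk_point(states))
  obs <- data.frame(patient_id = "A", window_index = windows, state = states)
  mae <- mean_time_mae(sl, obs)
  expect_equal(mae$median, 0)
  expect_equal(mae$q75, 0)
  # SOP mass 0.5 on the top state each window, observed always state 10
  m <- matrix(0, 16, 10); m[, 10] <- 0.5; m[, 1] <- 0.5
  sl2 <- list(A = structure(m, class = c("sop_matrix", "matrix"),
                            windows = windows, initial_state = 10L,
                            dimnames = list(windows, paste0("state", 1:10))))
  obs2 <- data.frame(patient_id = "A", window_index = windows, state = 10L)
  expect_equal(mean_time_mae(sl2, obs2)$median, 8)
  # misaligned windows are rejected
  expect_error(mean_time_mae(sl2, obs2[1:10, ]), "align")
})

test_that("transition calibration bins partition the predictions", {
  set.seed(97)
  tm <- default_true_model()
  tt <- simulate_transition_table(tm, 250, 19)
  fit <- suppressWarnings(suppressMessages(fit_po_markov(tm$spec, tt)))
  tc <- suppressMessages(transition_calibration(fit, tt))
  expect_setequal(unique(tc$state), c(10, 9, 1))
  for (s in c(10, 9, 1)) {
    sub <- tc[tc$state == s, ]
    expect_equal(sum(sub$n), nrow(tt))
    expect_true(all(sub$mean_predicted >= 0 & sub$mean_predicted <= 1))
    expect_true(all(diff(sub$mean_predicted) >= 0))
  }
})
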