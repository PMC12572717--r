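# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (day loops, path enumeration, direct formula
# transcription) so they share no code path with the implementation.

# Day-by-day supply-queue simulation: supply from each fill is stacked in a
# stockpile and one unit is consumed per day. Returns the covered-day logical
# vector over [0, horizon).
queue_coverage_oracle <- function(fill_day, days_supplied, horizon) {
  covered <- logical(horizon)
  stock <- 0
  for (day in 0:(horizon - 1)) {
    stock <- stock + sum(days_supplied[fill_day == day])
    if (stock > 0) {
      covered[day + 1] <- TRUE
      stock <- stock - 1
    }
  }
  covered
}

# covered/hospital days of window k by exhaustive day enumeration
window_days_oracle <- function(covered_vec, stay_days, k) {
  days <- (90 * (k - 1)):(90 * k - 1)
  in_cov <- days[days + 1 <= length(covered_vec)]
  cov <- sum(covered_vec[in_cov + 1])
  hosp <- length(setdiff(intersect(stay_days, days),
                         in_cov[covered_vec[in_cov + 1]]))
  c(cov, hosp)
}

# direct transcription of the restricted truncated-power basis formula
rcs_oracle <- function(x, knots) {
  k <- length(knots)
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in 1:(k - 2)) {
    for (i in seq_along(x)) {
      p3 <- function(u) if (u > 0) u^3 else 0
      v <- p3(x[i] - knots[j]) -
        p3(x[i] - knots[k - 1]) * (knots[k] - knots[j]) /
          (knots[k] - knots[k - 1]) +
        p3(x[i] - knots[k]) * (knots[k - 1] - knots[j]) /
          (knots[k] - knots[k - 1])
      out[i, j + 1] <- v / (knots[k] - knots[1])^2
    }
  }
  out
}

# linear-interpolation sample quantile written out by hand (type 7)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# random dispensing history: n_fills fills at random days (so gaps and
# overlapping early refills both occur), supplies 10-90 days
random_history <- function(n_fills = 20, horizon = 720) {
  list(day = sort(sample(0:(horizon - 90), n_fills, replace = TRUE)),
       supply = sample(10:90, n_fills, replace = TRUE),
       horizon = horizon)
}

# a toy proportional-odds fit with one linear covariate, categorical
# previous state and linear time, with the given parameters
make_toy_fit <- function(alpha, beta_x, beta_prev, beta_time, n_states = 10) {
  spec <- model_spec("linear:x", n_states = n_states,
                     centers = c(x = 0, time = 0))
  structure(list(
    alpha = setNames(alpha, paste0("y>=", 2:n_states)),
    beta = setNames(c(beta_x, beta_prev, beta_time),
                    c("x", paste0("prev=", 1:(n_states - 1)), "time")),
    loglik = NA_real_, vcov = NULL, n_obs = 0L,
    n_params = length(alpha) + 1 + n_states,
    converged = TRUE, spec = spec,
    knots = list(), centers = c(x = 0, time = 0),
    prev_levels = seq_len(n_states),
    var_ranges = list(x = c(-3, 3))
  ), class = "po_fit")
}

# ordered random intercepts for K states
random_alpha <- function(K) sort(rnorm(K - 1, 0, 1.5), decreasing = TRUE) -
  seq(0, 0.5, length.out = K - 1)
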