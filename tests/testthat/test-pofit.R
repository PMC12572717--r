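test_that("transition table is assembled as specified", {
  # hand-built 2-patient fixture
  windows <- expand.grid(patient_id = c("a", "b"), window_index = 1:20)
  windows <- windows[order(windows$patient_id, windows$window_index), ]
  windows$covered_days <- ifelse(windows$patient_id == "a", 90L, 60L)
  windows$hospital_days <- ifelse(windows$patient_id == "a" &
                                    windows$window_index == 2, 5L, 0L)
  windows$pdc <- compute_pdc(windows$covered_days, windows$hospital_days)
  windows$state <- map_pdc_to_state(windows$pdc)
  base <- data.frame(patient_id = c("a", "b"), age = c(70, 80),
                     chads_vasc = c(3, 6))
  tt <- build_transition_table(windows, base)
  expect_equal(nrow(tt), 32L)
  a <- tt[tt$patient_id == "a", ]
  expect_equal(a$time, 5:20)
  expect_true(all(a$y == 10L & a$y_prev == 10L))
  expect_equal(unique(a$days_w1), 90)
  expect_equal(unique(a$days_w2), 90)        # 90 + 5 capped at 90
  b <- tt[tt$patient_id == "b", ]
  expect_true(all(b$y == map_pdc_to_state(60 / 90)))
  expect_equal(unique(b$days_w3), 60)
  expect_equal(unique(b$age), 80)
  # a patient with missing windows is dropped with a message
  expect_message(
    tt2 <- build_transition_table(windows[-1, ], base), "missing windows")
  expect_equal(unique(tt2$patient_id), "b")
})

test_that("negative log-likelihood matches closed forms", {
  # two states: identical to binary logistic negative log-likelihood
  set.seed(41)
  n <- 200
  X <- cbind(rnorm(n), rnorm(n))
  alpha <- 0.4
  beta <- c(0.8, -0.5)
  p <- plogis(alpha + drop(X %*% beta))
  y <- 1L + rbinom(n, 1, p)
  nll <- po_neg_loglik(c(alpha, beta), X, y, 2)
  ref <- -sum(ifelse(y == 2, log(p), log(1 - p)))
  expect_equal(nll, ref, tolerance = 1e-12)
  # beta = 0 with marginal-cum-logit intercepts: multinomial entropy
  y5 <- sample(1:5, 500, replace = TRUE, prob = c(.1, .2, .3, .25, .15))
  phat <- as.numeric(table(factor(y5, levels = 1:5))) / 500
  alpha5 <- qlogis(rev(cumsum(rev(phat)))[-1])
  X5 <- matrix(rnorm(500), ncol = 1)
  nll5 <- po_neg_loglik(c(alpha5, 0), X5, y5, 5)
  expect_equal(nll5, -sum(table(factor(y5, levels = 1:5)) * log(phat)),
               tolerance = 1e-8)
  # hand-evaluated single observation
  a <- seq(3, -3, length.out = 9)
  nll1 <- po_neg_loglik(c(a, 0.5), matrix(1, 1, 1), 10L, 10)
  expect_equal(nll1, -log(plogis(a[9] + 0.5)), tolerance = 1e-12)
  # unordered intercepts hit the barrier, never NaN
  bad <- po_neg_loglik(c(rev(a), 0), matrix(1, 1, 1), 5L, 10)
  expect_true(is.finite(bad) && bad > 1e9)
})

test_that("analytic gradient and Hessian match finite differences", {
  set.seed(43)
  n <- 150
  X <- cbind(rnorm(n), runif(n))
  K <- 5
  y <- sample(1:K, n, replace = TRUE)
  for (r in 1:20) {
    theta <- c(sort(rnorm(K - 1), decreasing = TRUE) * 2, rnorm(2, 0, 0.5))
    g <- po_neg_loglik_grad(theta, X, y, K)
    h <- 1e-6
    g_num <- vapply(seq_along(theta), function(j) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (po_neg_loglik(tp, X, y, K) - po_neg_loglik(tm, X, y, K)) / (2 * h)
    }, numeric(1))
    expect_equal(g, g_num, tolerance = 1e-5)
  }
  # Hessian vs finite differences of the gradient at one point
  theta <- c(2, 1, 0, -1, 0.3, -0.2)
  H <- pdcmarkov:::po_nll_hess_cpp(theta, X, y, K)
  h <- 1e-5
  H_num <- vapply(seq_along(theta), function(j) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (po_neg_loglik_grad(tp, X, y, K) -
       po_neg_loglik_grad(tm, X, y, K)) / (2 * h)
  }, numeric(length(theta)))
  expect_equal(H, H_num, tolerance = 1e-4)
})

test_that("two-state fits match an independent binary logistic regression", {
  set.seed(47)
  n <- 800
  dat <- data.frame(x = rnorm(n), time = rep(5:12, each = n / 8),
                    y_prev = sample(1:2, n, replace = TRUE))
  eta <- 0.3 + 0.9 * dat$x - 0.4 * (dat$y_prev - 2) -
    0.1 * (dat$time - mean(dat$time))
  dat$y <- 1L + rbinom(n, 1, plogis(eta))
  sp <- model_spec("linear:x", prev_state = "linear", n_states = 2)
  fit <- fit_po_markov(sp, dat)
  expect_true(fit$converged)
  ref <- glm(I(y == 2) ~ x + I(y_prev - 2) + I(time - mean(time)),
             data = dat, family = binomial())
  expect_equal(unname(fit$alpha), unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(coef(ref)[-1]), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  # standard errors agree too (observed information)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("multi-state fits agree with MASS::polr", {
  skip_if_not_installed("MASS")
  set.seed(53)
  n <- 1200
  dat <- data.frame(x = rnorm(n), time = 5, y_prev = 5)
  a <- c(2, 1, 0, -1)
  eta <- 0.7 * dat$x
  cum <- cbind(1, plogis(outer(eta, a, `+`)), 0)
  pr <- cum[, 1:5] - cum[, 2:6]
  dat$y <- vapply(seq_len(n), function(i)
    sample(1:5, 1, prob = pr[i, ]), integer(1))
  sp <- model_spec("linear:x", prev_state = "linear", time = "linear",
                   n_states = 5)
  # constant y_prev and time give zero-variance columns, so the observed
  # information is singular: expected here
  fit <- suppressWarnings(fit_po_markov(sp, dat))
  # constant y_prev and time give zero-variance columns; compare x only
  ref <- MASS::polr(factor(y) ~ x, data = dat, Hess = TRUE)
  expect_equal(unname(fit$beta["x"]), unname(coef(ref)["x"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$alpha), unname(-ref$zeta), tolerance = 1e-4)
})

test_that("fitted cumulative probabilities are monotone and probs sum to 1", {
  set.seed(59)
  tm <- default_true_model()
  tt <- simulate_transition_table(tm, 150, 3)
  fit <- suppressWarnings(fit_po_markov(tm$spec, tt))
  expect_true(all(diff(fit$alpha) < 0))
  cov1 <- tt[1, c("age", "chads_vasc", paste0("days_w", 1:4))]
  for (s in c(1, 5, 10)) {
    p <- transition_probs(fit, cov1, s, 8)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
  # hand-computed logistic differences for a fixture fit
  toy <- make_toy_fit(alpha = seq(2.5, -2.5, length.out = 9), beta_x = 0.5,
                      beta_prev = rep(-1, 9), beta_time = -0.1)
  p <- transition_probs(toy, data.frame(x = 1.2), y_prev = 10, time = 3)
  eta <- 0.5 * 1.2 - 0.1 * 3
  cum <- c(1, plogis(seq(2.5, -2.5, length.out = 9) + eta), 0)
  expect_equal(unname(p), cum[1:10] - cum[2:11], tolerance = 1e-12)
})

test_that("shifting a covariate by a constant leaves probabilities unchanged", {
  set.seed(61)
  tm <- default_true_model()
  tt <- simulate_transition_table(tm, 200, 9)
  sp <- model_spec(c("linear:age", "linear:days_w4"))
  f1 <- fit_po_markov(sp, tt)
  tt2 <- tt
  tt2$age <- tt2$age + 25
  f2 <- fit_po_markov(sp, tt2)
  cov1 <- data.frame(age = 80, chads_vasc = 5, days_w1 = 90, days_w2 = 90,
                     days_w3 = 90, days_w4 = 85)
  cov2 <- cov1
  cov2$age <- cov1$age + 25
  p1 <- transition_probs(f1, cov1, 10, 8)
  p2 <- transition_probs(f2, cov2, 10, 8)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("AIC, likelihood-ratio test and intercept-only closed form", {
  f <- structure(list(loglik = -100, n_params = 5, n_obs = 50),
                 class = "po_fit")
  expect_equal(AIC(logLik.po_fit(f)), 210)
  f2 <- structure(list(loglik = -100, n_params = 5, n_obs = 50),
                  class = "po_fit")
  lr <- suppressWarnings(lr_test(f, f2))   # equal n_params warns, by design
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_warning(lr_test(structure(list(loglik = -90, n_params = 7),
                                   class = "po_fit"), f), "nested")
  # data independent of predictors: intercepts near marginal cumulative
  # log-odds, coefficients near zero
  set.seed(67)
  n <- 4000
  dat <- data.frame(x = rnorm(n), y_prev = sample(1:3, n, TRUE),
                    time = rep(5:8, each = n / 4),
                    y = sample(1:4, n, TRUE, prob = c(.1, .2, .3, .4)))
  sp <- model_spec("linear:x", prev_state = "linear", n_states = 4)
  fit <- fit_po_markov(sp, dat)
  z <- fit$beta / sqrt(diag(fit$vcov))[names(fit$beta)]
  expect_true(all(abs(z) < 4))
  phat <- as.numeric(table(dat$y)) / n
  expect_equal(unname(fit$alpha), qlogis(rev(cumsum(rev(phat)))[-1]),
               tolerance = 0.2)
})

test_that("partial effect curves reduce to design-matrix arithmetic", {
  set.seed(71)
  tm <- default_true_model()
  tt <- simulate_transition_table(tm, 400, 13)
  fit <- suppressWarnings(fit_po_markov(tm$spec, tt))
  # spline term: curve equals direct design-matrix multiplication
  pe <- partial_effect_curve(fit, "age", grid = seq(55, 95, length.out = 50))
  kn <- fit$knots$age
  B <- rcs_basis(seq(55, 95, length.out = 50), kn)
  B0 <- rcs_basis(fit$centers[["age"]], kn)
  direct <- drop((B - B0[rep(1, 50), ]) %*%
                   fit$beta[paste0("age", c("", "'", "''"))])
  expect_equal(pe$effect, direct, tolerance = 1e-10)
  expect_true(all(pe$upper >= pe$effect & pe$effect >= pe$lower))
  # the curve is zero at the centering constant
  pe0 <- partial_effect_curve(fit, "age", grid = fit$centers[["age"]])
  expect_equal(pe0$effect, 0, tolerance = 1e-12)
  # purely linear term: straight line with slope = coefficient
  sp <- model_spec(c("linear:age", "rcs4:days_w4"))
  fl <- suppressWarnings(fit_po_markov(sp, tt))
  pel <- partial_effect_curve(fl, "age", grid = c(60, 70, 80))
  slope <- diff(pel$effect) / 10
  expect_equal(slope, rep(unname(fl$beta["age"]), 2), tolerance = 1e-10)
  expect_error(partial_effect_curve(fit, "nope"), "not a model term")
})

test_that("fit serialization round-trips predictions bit for bit", {
  set.seed(73)
  tm <- default_true_model()
  tt <- simulate_transition_table(tm, 120, 17)
  fit <- suppressWarnings(fit_po_markov(tm$spec, tt))
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  fit2 <- read_fit_json(path)
  cov1 <- data.frame(age = 82, chads_vasc = 6, days_w1 = 90, days_w2 = 88,
                     days_w3 = 85, days_w4 = 90)
  p1 <- transition_probs(fit, cov1, 9, 12)
  p2 <- transition_probs(fit2, cov1, 9, 12)
  expect_equal(p1, p2, tolerance = 1e-12)
  s1 <- compute_sops(fit, cov1, 10)
  s2 <- compute_sops(fit2, cov1, 10)
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-12)
  unlink(path)
})
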