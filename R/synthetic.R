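#' Known ("true") transition model for synthetic cohorts
#'
#' A fully specified proportional-odds Markov transition model used as ground
#' truth: ordered intercepts, previous-state persistence coefficients, a
#' declining linear time trend, and covariate effects defined as closed-form
#' target shapes projected onto fixed-knot restricted-cubic-spline bases so
#' that the truth is exactly representable by the fitted model class.
#'
#' Shapes: age effect rising linearly to a plateau near 75; a modest positive
#' CHA2DS2-VASc effect (about `log(1.091)/2` per point); first-year window
#' effects nearly flat above ~89 covered days with a steep drop below, the
#' third and fourth windows steeper than the first two and interacting with
#' time (their effect attenuates over the horizon).
#'
#' @param n_states number of ordinal states (10).
#' @return Object of class `true_model`: `alpha`, named coefficient blocks,
#'   the full design-aligned coefficient vector `beta`, the [model_spec()]
#'   with frozen knots and centers, and the cohort marginal parameters used
#'   by [generate_cohort()].
#' @export
default_true_model <- function(n_states = 10L) {
  stopifnot(n_states == 10L)
  knots <- list(
    age = c(62, 72, 80, 92),
    chads_vasc = c(2, 4, 6, 8),
    days_w1 = c(35, 70, 85, 89),
    days_w2 = c(35, 70, 85, 89),
    days_w3 = c(35, 70, 85, 89),
    days_w4 = c(35, 70, 85, 89)
  )
  centers <- c(age = 78, chads_vasc = 5, days_w1 = 90, days_w2 = 90,
               days_w3 = 90, days_w4 = 90, time = 12.5)
  spec <- final_model_spec(n_states = n_states, knots = knots,
                           centers = centers)

  # closed-form target effect shapes (log-odds scale, zero at the centers)
  rise <- function(d) stats::plogis((d - 87.5) / 1.2) -
    stats::plogis((90 - 87.5) / 1.2)
  shapes <- list(
    age = function(a) 0.04 * (pmin(a, 75) - 75),
    chads_vasc = function(s) 0.0436 * (s - 5),
    days_w1 = function(d) 0.003 * (d - 90) + 0.3 * rise(d),
    days_w2 = function(d) 0.003 * (d - 90) + 0.3 * rise(d),
    days_w3 = function(d) 0.004 * (d - 90) + 0.6 * rise(d),
    days_w4 = function(d) 0.004 * (d - 90) + 0.6 * rise(d)
  )
  grids <- list(
    age = seq(50, 100, by = 0.5), chads_vasc = 1:9,
    days_w1 = 0:90, days_w2 = 0:90, days_w3 = 0:90, days_w4 = 0:90
  )
  project <- function(v) {
    B <- rcs_basis(grids[[v]], knots[[v]])
    unname(stats::lm.fit(cbind(1, B), shapes[[v]](grids[[v]]))$coefficients[-1])
  }
  bl <- lapply(names(shapes), project)
  names(bl) <- names(shapes)

  int_scale <- -0.07   # per centered-window unit: early effect stronger
  gamma <- list(days_w3 = int_scale * bl$days_w3,
                days_w4 = int_scale * bl$days_w4)
  prev_coef <- c(-8.0, -6.5, -5.8, -5.2, -4.6, -4.0, -3.2, -2.0, -0.4)
  # the interaction coefficients act on the raw spline columns; absorb the
  # centered offset B(center) . gamma into the linear time coefficient so the
  # time-varying part of the window effect is zero at the covariate centers
  time_coef <- -0.03 -
    drop(rcs_basis(centers[["days_w3"]], knots$days_w3) %*% gamma$days_w3) -
    drop(rcs_basis(centers[["days_w4"]], knots$days_w4) %*% gamma$days_w4)

  # reference state distribution at the centers (prev = 10, time centered);
  # strong persistence in the top state with most residual mass adjacent
  p_ref <- c(0.002, 0.00096, 0.00096, 0.00144, 0.00144, 0.00192, 0.00288,
             0.0048, 0.0336, 0.95)
  alpha_target <- stats::qlogis(rev(cumsum(rev(p_ref)))[-1])
  # design columns carry the raw (uncentered) basis; shift the intercepts so
  # the reference distribution holds at the covariate centers
  c0 <- sum(vapply(names(bl), function(v)
    drop(rcs_basis(centers[[v]], knots[[v]]) %*% bl[[v]]), numeric(1)))
  alpha <- alpha_target - c0
  names(alpha) <- paste0("y>=", 2:n_states)

  # full coefficient vector in build_design column order
  nm <- function(v) paste0(v, c("", "'", "''"))
  beta <- c(
    stats::setNames(bl$age, nm("age")),
    stats::setNames(bl$chads_vasc, nm("chads_vasc")),
    stats::setNames(bl$days_w1, nm("days_w1")),
    stats::setNames(bl$days_w2, nm("days_w2")),
    stats::setNames(bl$days_w3, nm("days_w3")),
    stats::setNames(gamma$days_w3, paste(nm("days_w3"), "* time")),
    stats::setNames(bl$days_w4, nm("days_w4")),
    stats::setNames(gamma$days_w4, paste(nm("days_w4"), "* time")),
    stats::setNames(prev_coef, paste0("prev=", 1:9)),
    c(time = time_coef)
  )

  structure(list(
    n_states = n_states, alpha = alpha, beta = beta,
    blocks = bl, gamma = gamma, prev_coef = prev_coef, time_coef = time_coef,
    knots = knots, centers = centers, spec = spec, shapes = shapes,
    cohort = list(
      age_median = 78, age_sd_lower = 7.4, age_sd_upper = 10.4,
      age_range = c(45, 100),
      score_prob = c(41, 211, 448, 644, 607, 474, 280, 112, 12) / 2829,
      miss_p0 = c(0.55, 0.52, 0.45, 0.42),   # P(no missed days), windows 1-4
      miss_mu = c(9, 14, 18, 22),            # mean missed days when missing
      miss_cap = c(45, 60, 90, 90),          # keeps new users eligible
      frailty_sdlog = 0.5
    )
  ), class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat("True proportional-odds Markov model (", x$n_states, " states, ",
      length(x$beta), " coefficients)\n", sep = "")
  invisible(x)
}

#' Treat a true model as a fitted model object
#'
#' Wraps a [default_true_model()] as a `po_fit` so that
#' [transition_probs()], [compute_sops()] and the simulators can be used with
#' the known truth.
#'
#' @param tm a `true_model`.
#' @return A `po_fit` (without a likelihood or covariance).
#' @export
as_po_fit <- function(tm) {
  stopifnot(inherits(tm, "true_model"))
  structure(list(
    alpha = tm$alpha, beta = tm$beta, loglik = NA_real_, vcov = NULL,
    n_obs = 0L, n_params = length(tm$alpha) + length(tm$beta),
    converged = TRUE, spec = tm$spec, knots = tm$knots, centers = tm$centers,
    prev_levels = seq_len(tm$n_states),
    var_ranges = list(age = c(50, 100), chads_vasc = c(1, 9),
                      days_w1 = c(0, 90), days_w2 = c(0, 90),
                      days_w3 = c(0, 90), days_w4 = c(0, 90))
  ), class = "po_fit")
}

# day-count range of each ordinal state (credited days out of 90); works
# elementwise on vectors and matrices
state_day_range <- function(s) {
  list(lo = ifelse(s == 10L, 81L, 9L * (s - 1L)),
       hi = ifelse(s == 10L, 90L, 9L * s - 1L))
}

# deterministic per-patient substream seeds (stable under cohort-size change)
patient_seed <- function(seed, i, stream = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 9973 + stream * 500009) %%
               2147483563)
}

# Phase-1 draws for one patient: covariates, first-year credited days, and
# the uniforms that later drive the state chain and day counts.
draw_patient_core <- function(pseed, cohort) {
  set.seed(pseed)
  u_side <- stats::runif(1)
  age <- if (u_side < 0.5)
    cohort$age_median - abs(stats::rnorm(1)) * cohort$age_sd_lower
  else
    cohort$age_median + abs(stats::rnorm(1)) * cohort$age_sd_upper
  age <- round(min(max(age, cohort$age_range[1]), cohort$age_range[2]))
  score <- sample.int(9L, 1L, prob = cohort$score_prob)
  z <- exp(stats::rnorm(1, 0, cohort$frailty_sdlog))
  d <- integer(4)
  for (k in 1:4) {
    gap <- if (stats::runif(1) < cohort$miss_p0[k]) 0
           else stats::rexp(1, 1 / cohort$miss_mu[k])
    missed <- min(round(z * gap), cohort$miss_cap[k], 90)
    d[k] <- 90L - as.integer(missed)
  }
  list(age = age, chads_vasc = score, days = d,
       u_state = stats::runif(16), u_days = stats::runif(16),
       u_place = stats::runif(20), u_hosp = stats::runif(20))
}

# linear-predictor pieces of the truth for a covariate table:
# base (covariate main effects) and slope (time coefficient incl. interaction)
truth_eta_parts <- function(tm, covs) {
  base <- rep(0, nrow(covs))
  for (v in names(tm$blocks))
    base <- base + drop(rcs_basis(covs[[v]], tm$knots[[v]]) %*% tm$blocks[[v]])
  slope <- tm$time_coef +
    drop(rcs_basis(covs$days_w3, tm$knots$days_w3) %*% tm$gamma$days_w3) +
    drop(rcs_basis(covs$days_w4, tm$knots$days_w4) %*% tm$gamma$days_w4)
  list(base = base, slope = slope)
}

# vectorized forward simulation of states over windows 5..20 given per-patient
# uniforms; y_prev0 is the state at window 4
simulate_states_u <- function(tm, covs, y_prev0, U) {
  n <- nrow(covs)
  parts <- truth_eta_parts(tm, covs)
  prev_full <- c(tm$prev_coef, 0)
  K <- tm$n_states
  states <- matrix(0L, n, 16L)
  y_prev <- as.integer(y_prev0)
  for (ti in 1:16) {
    t <- ti + 4L
    eta <- parts$base + prev_full[y_prev] + parts$slope * (t - tm$centers[["time"]])
    pr <- po_probs(tm$alpha, eta, K)
    cdf <- t(apply(pr, 1L, cumsum))
    y_prev <- 1L + as.integer(rowSums(cdf[, seq_len(K - 1L), drop = FALSE] <
                                        U[, ti]))
    states[, ti] <- y_prev
  }
  states
}

#' Simulate a transition table directly from a true model
#'
#' Draws baseline covariates and first-year credited days from the cohort
#' marginal model, sets the window-4 state from the fourth-window days, and
#' simulates the window 5-20 states from the true transition model. This is
#' the fast path for parameter-recovery studies (no claim-level records).
#'
#' @param tm a [default_true_model()].
#' @param n number of patients.
#' @param seed integer seed; all randomness flows from it through
#'   per-patient substreams.
#' @return A transition table as from [build_transition_table()].
#' @export
simulate_transition_table <- function(tm, n, seed) {
  stopifnot(n >= 1)
  core <- lapply(seq_len(n), function(i)
    draw_patient_core(patient_seed(seed, i), tm$cohort))
  covs <- data.frame(
    age = vapply(core, `[[`, numeric(1), "age"),
    chads_vasc = vapply(core, function(c) as.numeric(c$chads_vasc), numeric(1)),
    days_w1 = vapply(core, function(c) c$days[1], integer(1)),
    days_w2 = vapply(core, function(c) c$days[2], integer(1)),
    days_w3 = vapply(core, function(c) c$days[3], integer(1)),
    days_w4 = vapply(core, function(c) c$days[4], integer(1))
  )
  U <- t(vapply(core, `[[`, numeric(16), "u_state"))
  y4 <- map_pdc_to_state(compute_pdc(covs$days_w4, 0))
  states <- simulate_states_u(tm, covs, y4, U)
  ids <- sprintf("P%05d", seq_len(n))
  out <- data.frame(
    patient_id = rep(ids, each = 16L),
    time = rep(5:20, times = n),
    y = as.integer(t(states)),
    y_prev = as.integer(t(cbind(y4, states[, 1:15, drop = FALSE])))
  )
  out <- cbind(out, covs[rep(seq_len(n), each = 16L), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Emit claim-level records reproducing a day-level coverage vector
#'
#' Given a boolean vector of credited days, carves out occasional hospital
#' stays (in-hospital days are credited without a fill), splits the remaining
#' covered days into maximal runs, and chunks each run into fills of
#' `fill_size` days (last chunk the remainder). Later chunks are dispensed a
#' few days early with probability `early_refill_prob` (exercising the
#' carry-over rule) and the agent occasionally switches (exercising pooling).
#' Reconstruction through the PDC engine returns exactly the input credited
#' days per 90-day window.
#'
#' @param coverage logical vector, one element per day from the index date.
#' @param fill_size nominal days supplied per fill.
#' @param early_refill_prob probability a non-initial fill is dispensed
#'   1-7 days early.
#' @param switch_prob probability the patient switches agent once.
#' @param hospital_rate probability of one hospital stay (3-14 days) per
#'   360-day year.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return List with `fills` (`day`, `drug_code`, `days_supplied`) and
#'   `stays` (`admit_day`, `discharge_day`).
#' @export
generate_dispensing <- function(coverage, fill_size = 30L,
                                early_refill_prob = 0.3,
                                switch_prob = 0.117,
                                hospital_rate = 0.10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coverage <- as.logical(coverage)
  nd <- length(coverage)
  stays <- data.frame(admit_day = integer(), discharge_day = integer())
  fill_cov <- coverage

  if (nd > 0 && hospital_rate > 0) {
    n_years <- ceiling(nd / 360)
    for (yr in seq_len(n_years)) {
      if (stats::runif(1) >= hospital_rate) next
      len <- sample(3:14, 1L)
      lo_day <- (yr - 1L) * 360L
      wins <- which(lo_day + 90 * (0:3) < nd)
      if (!length(wins)) next
      w <- sample(rep(wins, 2L), 1L)      # rep() guards length-1 sample()
      w0 <- lo_day + 90L * (w - 1L)
      days <- seq.int(w0 + 1L, min(w0 + 90L, nd))
      cov_in <- days[fill_cov[days]]
      if (yr == 1L && w == 1L && length(cov_in))
        cov_in <- cov_in[-1L]             # keep the very first fill day
      if (length(cov_in) < 1L) next
      # the stay must be a contiguous block of covered days: carve from the
      # longest covered run inside the window
      brk <- c(TRUE, diff(cov_in) > 1L)
      rid <- cumsum(brk)
      best <- which.max(tabulate(rid))
      run <- cov_in[rid == best]
      h <- min(len, length(run))
      pos <- sample.int(length(run) - h + 1L, 1L)
      stay_days <- run[pos:(pos + h - 1L)]
      fill_cov[stay_days] <- FALSE
      stays <- rbind(stays, data.frame(admit_day = min(stay_days) - 1L,
                                       discharge_day = max(stay_days) - 1L))
    }
  }

  if (!any(fill_cov))
    return(list(fills = data.frame(day = integer(), drug_code = character(),
                                   days_supplied = integer()),
                stays = stays))

  # maximal runs of fill-covered days
  idx <- which(fill_cov)
  run_start <- idx[c(TRUE, diff(idx) > 1L)] - 1L  # 0-based day offsets
  run_end <- idx[c(diff(idx) > 1L, TRUE)]         # exclusive end = last+1
  agents <- c("apixaban", "rivaroxaban", "dabigatran")
  agent <- sample(agents, 1L, prob = c(0.66, 0.24, 0.10))
  day <- integer(0)
  supplied <- integer(0)
  for (r in seq_along(run_start)) {
    len <- run_end[r] - run_start[r]
    n_fill <- ceiling(len / fill_size)
    sizes <- rep(fill_size, n_fill)
    if (len %% fill_size) sizes[n_fill] <- len %% fill_size
    at <- run_start[r] + fill_size * (seq_len(n_fill) - 1L)
    early <- seq_len(n_fill) > 1L & stats::runif(n_fill) < early_refill_prob
    at[early] <- at[early] - sample(7L, sum(early), replace = TRUE)
    day <- c(day, at)
    supplied <- c(supplied, sizes)
  }
  drug <- rep(agent, length(day))
  if (length(day) > 1L && stats::runif(1) < switch_prob) {
    sw <- sample.int(length(day) - 1L, 1L) + 1L
    drug[sw:length(day)] <- sample(setdiff(agents, agent), 1L)
  }
  list(fills = data.frame(day = as.integer(day), drug_code = drug,
                          days_supplied = as.integer(supplied)),
       stays = stays)
}

#' Generate a synthetic dispensing cohort with known dynamics
#'
#' Emulates a new-user anticoagulant cohort: ages with median about 78 and
#' IQR about 73-85, CHA2DS2-VASc scores mostly 3-5, high first-year coverage,
#' strong state persistence and declining long-term adherence. Windows 1-4
#' arise from a claim-level first-year coverage process; windows 5-20 states
#' are drawn from the true transition model and converted back to day counts
#' and claims, so the whole pipeline (PDC engine included) can run end to end
#' and reproduce the stored ground truth exactly.
#'
#' All randomness flows from `seed` through counter-based per-patient
#' substreams, so patient `i`'s data is unchanged when `n` changes.
#'
#' @param n number of patients.
#' @param tm a [default_true_model()].
#' @param seed integer seed.
#' @param hospital_rate probability of a 3-14 day hospital stay per
#'   patient-year.
#' @param n_windows number of 90-day windows (default 20).
#' @param index_origin first calendar date that can serve as an index date.
#' @return Object of class `synthetic_cohort`: `baseline`, `dispensing`,
#'   `hospital` (claim-level CSV-ready data.frames), `truth` (the ground-truth
#'   window table with credited days and states), `true_model`, `seed`.
#' @export
generate_cohort <- function(n, tm = default_true_model(), seed = 1L,
                            hospital_rate = 0.10, n_windows = 20L,
                            index_origin = as.Date("2013-01-01")) {
  stopifnot(n >= 1)
  core <- lapply(seq_len(n), function(i)
    draw_patient_core(patient_seed(seed, i), tm$cohort))
  covs <- data.frame(
    age = vapply(core, `[[`, numeric(1), "age"),
    chads_vasc = vapply(core, function(c) as.numeric(c$chads_vasc), numeric(1)),
    days_w1 = vapply(core, function(c) c$days[1], integer(1)),
    days_w2 = vapply(core, function(c) c$days[2], integer(1)),
    days_w3 = vapply(core, function(c) c$days[3], integer(1)),
    days_w4 = vapply(core, function(c) c$days[4], integer(1))
  )
  U <- t(vapply(core, `[[`, numeric(16), "u_state"))
  V <- t(vapply(core, `[[`, numeric(16), "u_days"))
  y4 <- map_pdc_to_state(compute_pdc(covs$days_w4, 0))
  states <- simulate_states_u(tm, covs, y4, U)

  # day counts for windows 5..20 drawn uniformly within each state's range
  rng <- state_day_range(states)
  d_late <- matrix(as.integer(rng$lo + floor(pmin(V, 1 - 1e-12) *
                                               (rng$hi - rng$lo + 1L))),
                   nrow = n)

  ids <- sprintf("P%05d", seq_len(n))
  set.seed(patient_seed(seed, 0L, stream = 2L))
  index_dates <- index_origin + sample.int(1800L, n, replace = TRUE)

  disp <- vector("list", n)
  hosp <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    d_all <- c(covs$days_w1[i], covs$days_w2[i], covs$days_w3[i],
               covs$days_w4[i], d_late[i, ])[seq_len(n_windows)]
    place <- core[[i]]$u_place[seq_len(n_windows)]
    cov_vec <- logical(90L * n_windows)
    for (k in seq_len(n_windows)) {
      dk <- d_all[k]
      if (dk == 0L) next
      off <- if (k == 1L) 0L else floor(place[k] * (90L - dk + 1L))
      cov_vec[90L * (k - 1L) + off + seq_len(dk)] <- TRUE
    }
    set.seed(patient_seed(seed, i, stream = 1L))
    rec <- generate_dispensing(cov_vec, hospital_rate = hospital_rate)
    hosp_days_w <- integer(n_windows)
    if (nrow(rec$stays)) {
      for (s in seq_len(nrow(rec$stays))) {
        sd <- rec$stays$admit_day[s]:rec$stays$discharge_day[s]
        kw <- sd %/% 90L + 1L
        tb <- table(kw)
        hosp_days_w[as.integer(names(tb))] <-
          hosp_days_w[as.integer(names(tb))] + as.integer(tb)
      }
    }
    pdc <- compute_pdc(d_all - hosp_days_w, hosp_days_w)
    truth[[i]] <- data.frame(
      patient_id = ids[i], window_index = seq_len(n_windows),
      covered_days = as.integer(d_all - hosp_days_w),
      hospital_days = hosp_days_w,
      pdc = pdc, state = map_pdc_to_state(pdc)
    )
    disp[[i]] <- data.frame(
      patient_id = ids[i],
      dispense_date = index_dates[i] + rec$fills$day,
      drug_code = rec$fills$drug_code,
      days_supplied = rec$fills$days_supplied
    )
    hosp[[i]] <- if (nrow(rec$stays)) data.frame(
      patient_id = ids[i],
      admit_date = index_dates[i] + rec$stays$admit_day,
      discharge_date = index_dates[i] + rec$stays$discharge_day
    ) else NULL
  }

  structure(list(
    baseline = data.frame(patient_id = ids, index_date = index_dates,
                          age = covs$age, chads_vasc = covs$chads_vasc),
    dispensing = do.call(rbind, disp),
    hospital = {
      h <- do.call(rbind, hosp[!vapply(hosp, is.null, logical(1))])
      if (is.null(h)) data.frame(patient_id = character(),
                                 admit_date = as.Date(character()),
                                 discharge_date = as.Date(character()))
      else h
    },
    truth = do.call(rbind, truth),
    true_model = tm, seed = seed, n = n
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic dispensing cohort:", x$n, "patients,",
      nrow(x$dispensing), "fills,", nrow(x$hospital), "hospital stays",
      "(seed", x$seed, ")\n")
  invisible(x)
}

#' Monte-Carlo state trajectories for one subject
#'
#' Forward-simulates `n_sims` state chains from a model's one-step transition
#' probabilities and returns the empirical occupancy frequencies — an
#' independent check of the recursive SOP computation.
#'
#' @param fit a `po_fit` (fitted, or [as_po_fit()] of a true model).
#' @param covariates one-row data.frame of baseline covariates.
#' @param initial_state state at the window before the first one simulated.
#' @param n_sims number of chains.
#' @param seed integer seed.
#' @param windows simulated windows (default `5:20`).
#' @return `sop_matrix` of empirical frequencies (`length(windows)` rows).
#' @export
simulate_trajectories <- function(fit, covariates, initial_state, n_sims,
                                  seed = 1L, windows = 5:20) {
  stopifnot(n_sims >= 1)
  K <- fit$spec$n_states
  P <- transition_array(fit, covariates, windows)
  Tn <- length(windows)
  set.seed(seed)
  y <- rep.int(as.integer(initial_state), n_sims)
  freq <- matrix(0, Tn, K, dimnames = list(windows, paste0("state", 1:K)))
  for (ti in seq_len(Tn)) {
    cdf <- t(apply(P[ti, , ], 1L, cumsum))
    u <- stats::runif(n_sims)
    y <- 1L + as.integer(rowSums(cdf[y, seq_len(K - 1L), drop = FALSE] < u))
    freq[ti, ] <- tabulate(y, nbins = K) / n_sims
  }
  structure(freq, class = c("sop_matrix", "matrix"), windows = windows,
            initial_state = initial_state)
}

#' Simulate observed state sequences from a fitted model
#'
#' Draws one state chain per subject from the model's transition
#' probabilities, starting at each subject's observed window-4 state. Used
#' for self-calibration checks (data simulated from the evaluated model).
#'
#' @param fit a `po_fit`.
#' @param subjects data.frame of baseline covariates, one row per subject.
#' @param initial_state integer vector of starting states (recycled).
#' @param seed integer seed.
#' @param windows simulated windows.
#' @return Integer matrix, subjects x windows.
#' @export
simulate_from_model <- function(fit, subjects, initial_state, seed = 1L,
                                windows = 5:20) {
  n <- nrow(subjects)
  initial_state <- rep_len(initial_state, n)
  K <- fit$spec$n_states
  Tn <- length(windows)
  set.seed(seed)
  U <- matrix(stats::runif(n * Tn), n, Tn)
  out <- matrix(0L, n, Tn, dimnames = list(NULL, windows))
  for (i in seq_len(n)) {
    P <- transition_array(fit, subjects[i, , drop = FALSE], windows)
    y <- initial_state[i]
    for (ti in seq_len(Tn)) {
      cdf <- cumsum(P[ti, y, ])
      y <- 1L + sum(cdf[seq_len(K - 1L)] < U[i, ti])
      out[i, ti] <- y
    }
  }
  out
}
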