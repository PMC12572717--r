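#' Build the transition table from windowed adherence states
#'
#' One row per patient and outcome window `t` in `first_window..horizon`
#' (default 5..20, i.e. years 2-5): the state `y` at `t`, the previous state
#' `y_prev` at `t - 1`, the window index `time`, the baseline covariates and
#' the credited days of the four first-year windows
#' (`days_wk = min(covered_days + hospital_days, 90)`). Patients with any
#' missing window are dropped with a message.
#'
#' @param windows data.frame from [build_cohort_windows()].
#' @param baseline data.frame with `patient_id`, `age`, `chads_vasc`.
#' @param first_window first outcome window (default 5).
#' @param horizon last outcome window (default 20).
#' @return data.frame with columns `patient_id`, `time`, `y`, `y_prev`,
#'   `age`, `chads_vasc`, `days_w1`..`days_w4`.
#' @export
build_transition_table <- function(windows, baseline, first_window = 5L,
                                   horizon = 20L) {
  stopifnot(first_window >= 2L, horizon >= first_window)
  cnt <- table(windows$patient_id)
  full <- names(cnt)[cnt >= horizon]
  dropped <- setdiff(unique(windows$patient_id), full)
  if (length(dropped))
    message(length(dropped), " patient(s) with missing windows dropped")
  w <- windows[windows$patient_id %in% full &
                 windows$window_index <= horizon, , drop = FALSE]
  w$patient_id <- as.character(w$patient_id)  # drop unused factor levels
  w <- w[order(w$patient_id, w$window_index), , drop = FALSE]
  credited <- pmin(w$covered_days + w$hospital_days, 90)

  wide_states <- split(w$state, w$patient_id)
  wide_days <- split(credited, w$patient_id)
  ids <- names(wide_states)
  tt <- first_window:horizon
  nt <- length(tt)
  out <- data.frame(
    patient_id = rep(ids, each = nt),
    time = rep(tt, times = length(ids)),
    y = unlist(lapply(wide_states, function(s) s[tt]), use.names = FALSE),
    y_prev = unlist(lapply(wide_states, function(s) s[tt - 1L]),
                    use.names = FALSE)
  )
  d14 <- do.call(rbind, lapply(wide_days, function(d) d[1:4]))
  colnames(d14) <- paste0("days_w", 1:4)
  out <- cbind(out, d14[rep(seq_along(ids), each = nt), , drop = FALSE])
  bl <- baseline[match(out$patient_id, baseline$patient_id),
                 c("age", "chads_vasc"), drop = FALSE]
  if (anyNA(bl)) stop("baseline covariates missing for some patients")
  out$age <- bl$age
  out$chads_vasc <- bl$chads_vasc
  rownames(out) <- NULL
  out
}

#' Negative log-likelihood of the proportional-odds model
#'
#' `theta` packs the `n_states - 1` cumulative-logit intercepts
#' (for `P(Y >= j)`, `j = 2..n_states`) followed by the coefficient vector.
#' Unordered intercepts produce non-positive category probabilities and
#' return a large finite barrier value rather than `NaN`.
#'
#' @param theta parameter vector, length `(n_states - 1) + ncol(X)`.
#' @param X design matrix.
#' @param y integer outcomes in `1..n_states`.
#' @param n_states number of ordinal states.
#' @return Scalar negative log-likelihood.
#' @export
po_neg_loglik <- function(theta, X, y, n_states) {
  po_nll_cpp(as.numeric(theta), as.matrix(X), as.integer(y),
             as.integer(n_states))
}

#' @rdname po_neg_loglik
#' @return `po_neg_loglik_grad`: the analytic gradient vector.
#' @export
po_neg_loglik_grad <- function(theta, X, y, n_states) {
  po_nll_grad_cpp(as.numeric(theta), as.matrix(X), as.integer(y),
                  as.integer(n_states))
}

po_start <- function(y, n_states, p) {
  cum <- vapply(2:n_states, function(j) mean(y >= j), numeric(1))
  cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
  alpha <- stats::qlogis(cum)
  # enforce strict ordering at the start in case of empty categories
  for (j in seq_along(alpha)[-1])
    if (alpha[j] >= alpha[j - 1]) alpha[j] <- alpha[j - 1] - 1e-4
  c(alpha, rep(0, p))
}

#' Fit a first-order proportional-odds Markov transition model
#'
#' Maximum-likelihood fit of the cumulative-logit model
#' `P(Y >= j | x) = plogis(alpha_j + x beta)` to a transition table, with the
#' design built by [build_design()]. Higher linear predictor means higher
#' (better) adherence states. Estimation is by Newton-Raphson with the
#' analytic gradient and Hessian, a Levenberg-style ridge on non-descending
#' steps, and a BFGS fallback; the start is the intercept-only solution
#' (marginal cumulative log-odds). The fit is deterministic. Non-convergence
#' is flagged, not thrown.
#'
#' @param spec a [model_spec()].
#' @param transitions transition table from [build_transition_table()].
#' @param tol convergence tolerance: the fit is flagged converged when the
#'   gradient sup-norm is below `tol * (1 + |loglik|)`.
#' @param maxit maximum Newton iterations.
#' @param knots,centers optional overrides passed to [build_design()].
#' @return Object of class `po_fit`: `alpha` (ordered intercepts), `beta`
#'   (named coefficients), `loglik`, `vcov` (inverse observed information),
#'   `n_obs`, `n_params`, `converged`, plus the spec, knots, centers and
#'   previous-state levels needed to rebuild prediction rows.
#' @export
fit_po_markov <- function(spec, transitions, tol = 1e-8, maxit = 100L,
                          knots = NULL, centers = NULL) {
  des <- build_design(spec, transitions, knots = knots, centers = centers)
  X <- des$X
  y <- as.integer(transitions$y)
  K <- spec$n_states
  if (length(unique(y)) < 2L)
    stop("need observations in at least 2 outcome categories")
  if (any(y < 1L | y > K)) stop("outcome states outside 1..n_states")
  p <- ncol(X)

  fn <- function(th) po_nll_cpp(th, X, y, K)
  gr <- function(th) po_nll_grad_cpp(th, X, y, K)

  theta <- po_start(y, K, p)
  val <- fn(theta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    g <- gr(theta)
    if (max(abs(g)) < tol * (1 + abs(val))) {
      converged <- TRUE
      break
    }
    H <- po_nll_hess_cpp(theta, X, y, K)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    ridge <- 1e-4 * mean(abs(diag(H)))
    while (is.null(step) && ridge < 1e12) {
      step <- tryCatch(solve(H + diag(ridge, nrow(H)), g),
                       error = function(e) NULL)
      ridge <- ridge * 10
    }
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- theta - lam * step
      vc <- fn(cand)
      if (vc < val || lam < 1e-10) break
      lam <- lam / 2
    }
    if (vc >= val) break  # no descent possible
    theta <- cand
    val <- vc
  }
  if (!converged) {
    # quasi-Newton fallback from wherever Newton stopped
    o <- stats::optim(theta, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (o$value <= val) {
      theta <- o$par
      val <- o$value
    }
    g <- gr(theta)
    converged <- max(abs(g)) < tol * (1 + abs(val))
  }

  H <- po_nll_hess_cpp(theta, X, y, K)
  vcov <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; vcov unavailable")
    NULL
  })
  alpha <- theta[seq_len(K - 1)]
  names(alpha) <- paste0("y>=", 2:K)
  beta <- theta[K - 1 + seq_len(p)]
  names(beta) <- colnames(X)
  if (!is.null(vcov))
    dimnames(vcov) <- list(c(names(alpha), names(beta)),
                           c(names(alpha), names(beta)))
  structure(list(
    alpha = alpha, beta = beta, loglik = -val, vcov = vcov,
    n_obs = length(y), n_params = (K - 1) + p, converged = converged,
    spec = spec, knots = des$knots, centers = des$centers,
    prev_levels = des$prev_levels,
    var_ranges = lapply(transitions[vapply(spec$terms, `[[`, character(1),
                                           "var")], range)
  ), class = "po_fit")
}

#' @export
print.po_fit <- function(x, ...) {
  cat("Proportional-odds Markov transition model\n")
  cat("  ", x$spec$n_states, "states;", x$n_obs, "transitions;",
      x$n_params, "parameters\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " AIC:", format(-2 * x$loglik + 2 * x$n_params, digits = 8), "\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
logLik.po_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.po_fit <- function(object, ...) object$vcov

#' @export
coef.po_fit <- function(object, ...) c(object$alpha, object$beta)

#' Likelihood-ratio test between two fits
#'
#' @param fit_nested,fit_full [fit_po_markov()] fits, the first nested in the
#'   second. A non-nested pair (non-positive df or negative statistic) is
#'   still computed, with a warning.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(fit_nested, fit_full) {
  stat <- 2 * (fit_full$loglik - fit_nested$loglik)
  df <- fit_full$n_params - fit_nested$n_params
  if (df <= 0 || stat < 0)
    warning("models do not look nested (df = ", df,
            ", statistic = ", format(stat), ")")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, max(df, 1L), lower.tail = FALSE))
}

#' One-step transition probabilities
#'
#' Probability vector over the `n_states` outcome states for a subject with
#' the given baseline covariates, previous state and window index, from a
#' fitted model. Covariates outside the spline knots are allowed (the basis
#' is linear in the tails).
#'
#' @param fit a [fit_po_markov()] fit.
#' @param covariates one-row data.frame (or named list) with the model's
#'   covariates (e.g. `age`, `chads_vasc`, `days_w1`..`days_w4`).
#' @param y_prev previous state in `1..n_states`.
#' @param time window index.
#' @return Numeric probability vector of length `n_states`, summing to 1.
#' @export
transition_probs <- function(fit, covariates, y_prev, time) {
  if (y_prev < 1 || y_prev > fit$spec$n_states)
    stop("y_prev outside 1..n_states")
  nd <- as.data.frame(covariates)
  nd$y_prev <- y_prev
  nd$time <- time
  eta <- predict_eta(fit, nd)
  po_probs(fit$alpha, eta, fit$spec$n_states)[1, ]
}

# linear predictor(s) for new transition rows
predict_eta <- function(fit, newdata) {
  des <- build_design(fit$spec, newdata, knots = fit$knots,
                      centers = fit$centers, prev_levels = fit$prev_levels)
  drop(des$X %*% fit$beta)
}

# category probabilities from intercepts and linear predictors (rowwise)
po_probs <- function(alpha, eta, n_states) {
  cum <- cbind(1, stats::plogis(outer(eta, alpha, `+`)), 0)
  pr <- cum[, seq_len(n_states), drop = FALSE] -
    cum[, 1 + seq_len(n_states), drop = FALSE]
  colnames(pr) <- paste0("state", seq_len(n_states))
  pr
}

#' Fit and compare the candidate-model ladder
#'
#' Fits every specification from [ladder_specs()] on the same transition
#' table, reports AIC and the likelihood-ratio test of each model against the
#' basic model, and flags the minimum-AIC specification as final.
#' Knots are placed once on the transition table and shared across members so
#' that nested comparisons are exact.
#'
#' @param transitions transition table.
#' @param specs named list of [model_spec()]s (default [ladder_specs()]).
#' @param n_states number of outcome states.
#' @param ... passed to [fit_po_markov()].
#' @return List with `table` (data.frame: model, n_params, loglik, aic,
#'   lr_stat, lr_df, lr_p, converged, final) and `fits` (named list of
#'   `po_fit`s).
#' @export
model_ladder <- function(transitions, specs = NULL, n_states = 10L, ...) {
  if (is.null(specs)) specs <- ladder_specs(n_states = n_states)
  all_vars <- unique(unlist(lapply(specs, function(s)
    vapply(s$terms, `[[`, character(1), "var"))))
  kn <- lapply(all_vars, function(v) choose_knots(transitions[[v]], v))
  names(kn) <- all_vars
  fits <- lapply(specs, function(s) {
    tryCatch(fit_po_markov(s, transitions, knots = kn[
      vapply(s$terms, `[[`, character(1), "var")], ...),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  ref <- fits[["basic"]]
  rows <- lapply(names(specs), function(nm) {
    f <- fits[[nm]]
    if (is.null(f))
      return(data.frame(model = nm, n_params = NA, loglik = NA, aic = NA,
                        lr_stat = NA, lr_df = NA, lr_p = NA,
                        converged = FALSE))
    lr <- if (nm == "basic" || is.null(ref)) list(statistic = NA, df = NA,
                                                  p_value = NA)
          else suppressWarnings(lr_test_ordered(ref, f))
    data.frame(model = nm, n_params = f$n_params, loglik = f$loglik,
               aic = -2 * f$loglik + 2 * f$n_params,
               lr_stat = lr$statistic, lr_df = lr$df, lr_p = lr$p_value,
               converged = f$converged)
  })
  tab <- do.call(rbind, rows)
  tab$final <- FALSE
  conv <- which(tab$converged & !is.na(tab$aic))
  if (length(conv)) tab$final[conv[which.min(tab$aic[conv])]] <- TRUE
  list(table = tab, fits = fits)
}

# LR test with the smaller model taken as nested, whichever argument it is
lr_test_ordered <- function(f1, f2) {
  if (f1$n_params <= f2$n_params) lr_test(f1, f2) else lr_test(f2, f1)
}

#' Partial-effect curve of a model term
#'
#' Log-odds effect of moving `variable` along `grid` while every other
#' variable is held at its centering constant, the previous state at the
#' reference (highest) state and time at its center; the effect is relative
#' to `variable` at its own center, so the curve passes through zero there.
#' Pointwise 95 percent confidence bands come from the delta method on the
#' coefficient covariance.
#'
#' @param fit a [fit_po_markov()] fit.
#' @param variable model variable name.
#' @param grid numeric grid (default: 50 points over the training range).
#' @param level confidence level.
#' @return data.frame with `grid`, `effect`, `lower`, `upper`.
#' @export
partial_effect_curve <- function(fit, variable, grid = NULL, level = 0.95) {
  vars <- vapply(fit$spec$terms, `[[`, character(1), "var")
  if (!variable %in% vars) stop("'", variable, "' is not a model term")
  if (is.null(grid)) {
    r <- fit$var_ranges[[variable]]
    grid <- seq(r[1], r[2], length.out = 50)
  }
  base <- as.list(fit$centers[vars])
  mk_rows <- function(vals) {
    nd <- as.data.frame(base)[rep(1, length(vals)), , drop = FALSE]
    nd[[variable]] <- vals
    nd$y_prev <- max(fit$prev_levels)
    nd$time <- fit$centers[["time"]]
    build_design(fit$spec, nd, knots = fit$knots, centers = fit$centers,
                 prev_levels = fit$prev_levels)$X
  }
  Xg <- mk_rows(grid)
  X0 <- mk_rows(fit$centers[[variable]])
  D <- Xg - X0[rep(1, nrow(Xg)), , drop = FALSE]
  eff <- drop(D %*% fit$beta)
  se <- rep(NA_real_, length(eff))
  if (!is.null(fit$vcov)) {
    Vb <- fit$vcov[names(fit$beta), names(fit$beta), drop = FALSE]
    se <- sqrt(pmax(rowSums((D %*% Vb) * D), 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(grid = grid, effect = eff,
             lower = eff - z * se, upper = eff + z * se)
}
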