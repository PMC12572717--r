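#' Expected numeric state of a probability vector
#'
#' @param p probability vector over the ordinal states (must sum to 1).
#' @return `sum(j * p_j)`, in `[1, length(p)]`.
#' @export
expected_state <- function(p) {
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  sum(seq_along(p) * p)
}

# long prediction table from a named list of SOP matrices and an observed
# window table: patient_id, window, expected (predicted), observed
sop_prediction_table <- function(sop_list, observed) {
  stopifnot(!is.null(names(sop_list)))
  rows <- lapply(names(sop_list), function(id) {
    s <- sop_list[[id]]
    data.frame(patient_id = id, window = attr(s, "windows"),
               expected = drop(unclass(s) %*% seq_len(ncol(s))))
  })
  pred <- do.call(rbind, rows)
  key <- paste(observed$patient_id, observed$window_index)
  pred$observed <- observed$state[match(paste(pred$patient_id, pred$window),
                                        key)]
  if (anyNA(pred$observed)) stop("observed states missing for some windows")
  pred
}

decile_groups <- function(x, ids, g = 10L) {
  # stable rank on subject id breaks ties deterministically
  o <- order(x, ids)
  grp <- integer(length(x))
  grp[o] <- as.integer(cut(seq_along(x), breaks = g, labels = FALSE))
  grp
}

#' Subject-level (optionally time-stratified) calibration table
#'
#' Each analysis unit is one subject (its mean predicted expected state and
#' mean observed state over the windows in scope). Units are split into
#' deciles of the mean predicted value — sizes differing by at most one, ties
#' broken by subject id — and the decile means of predicted and observed are
#' tabulated. With `strata`, the grouping is done within each named window
#' stratum; the defaults mirror an early (window 5) / middle (6-12) /
#' late (13-20) split of the horizon.
#'
#' @param predictions data.frame with `patient_id`, `window`, `expected`
#'   (predicted expected state) and `observed` (observed state), e.g. from a
#'   set of SOP matrices; see [evaluate_model()].
#' @param strata `NULL` (subject-level over all windows), `"default"` for the
#'   early/middle/late split, or a named list of window vectors.
#' @param groups number of groups (default 10 deciles; fewer units give
#'   fewer groups, with a message).
#' @return data.frame with `stratum` (if any), `group`, `mean_predicted`,
#'   `mean_observed`, `n`.
#' @export
subject_calibration <- function(predictions, strata = NULL, groups = 10L) {
  strata <- resolve_strata(strata)
  one <- function(df, label) {
    agg <- stats::aggregate(cbind(expected, observed) ~ patient_id,
                            data = df, FUN = mean)
    g <- min(groups, nrow(agg))
    if (g < groups) message("only ", nrow(agg), " subjects; using ", g,
                            " groups")
    grp <- decile_groups(agg$expected, agg$patient_id, g)
    out <- data.frame(
      stratum = label,
      group = sort(unique(grp)),
      mean_predicted = as.numeric(tapply(agg$expected, grp, mean)),
      mean_observed = as.numeric(tapply(agg$observed, grp, mean)),
      n = as.integer(table(grp))
    )
    out
  }
  if (is.null(strata)) return(one(predictions, "all"))
  do.call(rbind, lapply(names(strata), function(nm)
    one(predictions[predictions$window %in% strata[[nm]], , drop = FALSE], nm)))
}

resolve_strata <- function(strata) {
  if (is.null(strata)) return(NULL)
  if (identical(strata, "default"))
    return(list(early = 5L, middle = 6:12, late = 13:20))
  stopifnot(is.list(strata), !is.null(names(strata)))
  strata
}

#' GAM-smoothed subject-level calibration curve
#'
#' Penalized-spline scatterplot smoother (generalized additive model, GCV
#' smoothing) of observed state on predicted expected state at the
#' subject-window level, evaluated on a 100-point grid over the predicted
#' range. Degenerate (constant) predictions return a flat line at the mean
#' observed value.
#'
#' @param predictions as in [subject_calibration()].
#' @param grid_n grid size (default 100).
#' @return data.frame with `predicted`, `smoothed`.
#' @export
smoothed_calibration <- function(predictions, grid_n = 100L) {
  x <- predictions$expected
  y <- predictions$observed
  gx <- seq(min(x), max(x), length.out = grid_n)
  ux <- length(unique(x))
  if (ux < 4L)
    return(data.frame(predicted = gx, smoothed = rep(mean(y), grid_n)))
  kk <- min(10L, ux - 1L)
  fit <- mgcv::gam(y ~ s(x, k = kk))
  data.frame(predicted = gx,
             smoothed = as.numeric(stats::predict(fit,
                                                  newdata = data.frame(x = gx))))
}

#' One-step transition-probability calibration
#'
#' For each state of interest, the fitted one-step probability of moving to
#' that state is computed for every transition row, binned into deciles
#' (equal-count, ties broken by row order), and compared with the observed
#' event fraction per bin.
#'
#' @param fit a [fit_po_markov()] fit.
#' @param transitions the transition table the probabilities are evaluated
#'   on.
#' @param states states of interest (default `c(10, 9, 1)`: the extreme and
#'   next-highest PDC states).
#' @return data.frame with `state`, `group`, `mean_predicted`,
#'   `event_fraction`, `n`.
#' @export
transition_calibration <- function(fit, transitions, states = c(10L, 9L, 1L)) {
  des <- build_design(fit$spec, transitions, knots = fit$knots,
                      centers = fit$centers, prev_levels = fit$prev_levels)
  eta <- drop(des$X %*% fit$beta)
  pr <- po_probs(fit$alpha, eta, fit$spec$n_states)
  out <- lapply(states, function(s) {
    p <- pr[, s]
    grp <- decile_groups(p, seq_along(p))
    obs <- as.numeric(transitions$y == s)
    data.frame(state = s, group = sort(unique(grp)),
               mean_predicted = as.numeric(tapply(p, grp, mean)),
               event_fraction = as.numeric(tapply(obs, grp, mean)),
               n = as.integer(table(grp)))
  })
  do.call(rbind, out)
}

# subjects x windows x states array from a list of SOP matrices
sop_array <- function(sop_list) {
  s1 <- sop_list[[1]]
  arr <- array(0, dim = c(length(sop_list), nrow(s1), ncol(s1)),
               dimnames = list(names(sop_list), rownames(s1), colnames(s1)))
  for (i in seq_along(sop_list)) arr[i, , ] <- unclass(sop_list[[i]])
  arr
}

#' SOP distribution width (discrimination) per state
#'
#' For every state and window, the interquartile-range length (75th minus
#' 25th percentile, linear-interpolation quantile convention) of the state
#' occupancy probability across subjects; wider distributions mean the model
#' separates subjects more strongly for that state. The time average over
#' windows summarizes each state.
#'
#' @param sop_list named list of per-subject [compute_sops()] matrices (all
#'   on the same windows).
#' @return List with `by_window` (data.frame `state`, `window`, `width`) and
#'   `average` (named numeric, time-averaged width per state).
#' @export
sop_width <- function(sop_list) {
  arr <- sop_array(sop_list)
  if (dim(arr)[1] < 2L) message("fewer than 2 subjects; widths are 0")
  Tn <- dim(arr)[2]
  K <- dim(arr)[3]
  w <- matrix(0, Tn, K)
  for (t in seq_len(Tn))
    for (j in seq_len(K)) {
      q <- stats::quantile(arr[, t, j], c(0.25, 0.75), type = 7, names = FALSE)
      w[t, j] <- q[2] - q[1]
    }
  by_window <- data.frame(
    state = rep(seq_len(K), each = Tn),
    window = rep(as.integer(dimnames(arr)[[2]]), times = K),
    width = as.numeric(w)
  )
  avg <- colMeans(w)
  names(avg) <- paste0("state", seq_len(K))
  list(by_window = by_window, average = avg)
}

#' Bootstrap internal validation of SOP distribution width
#'
#' Resamples subjects with replacement `reps` times, recomputes the
#' time-averaged width per state (and per window), and reports the bootstrap
#' median and the 2.5/97.5 percentile envelope. Reproducible under a fixed
#' seed.
#'
#' @param sop_list as in [sop_width()].
#' @param reps number of bootstrap repetitions (default 100).
#' @param seed integer seed.
#' @return List with `average` (data.frame `state`, `median`, `lower`,
#'   `upper`) and `by_window` (data.frame `state`, `window`, `median`,
#'   `lower`, `upper`).
#' @export
bootstrap_widths <- function(sop_list, reps = 100L, seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1")
  arr <- sop_array(sop_list)
  n <- dim(arr)[1]
  Tn <- dim(arr)[2]
  K <- dim(arr)[3]
  set.seed(seed)
  avg_reps <- array(0, dim = c(reps, K))
  win_reps <- array(0, dim = c(reps, Tn, K))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    for (t in seq_len(Tn))
      for (j in seq_len(K)) {
        q <- stats::quantile(arr[idx, t, j], c(0.25, 0.75), type = 7,
                             names = FALSE)
        win_reps[r, t, j] <- q[2] - q[1]
      }
    avg_reps[r, ] <- colMeans(win_reps[r, , , drop = FALSE][1, , ])
  }
  qs <- function(v) stats::quantile(v, c(0.5, 0.025, 0.975), type = 7,
                                    names = FALSE)
  avg <- t(apply(avg_reps, 2L, qs))
  windows <- as.integer(dimnames(arr)[[2]])
  bw <- do.call(rbind, lapply(seq_len(K), function(j) {
    m <- t(apply(win_reps[, , j, drop = FALSE][, , 1], 2L, qs))
    data.frame(state = j, window = windows,
               median = m[, 1], lower = m[, 2], upper = m[, 3])
  }))
  list(average = data.frame(state = seq_len(K), median = avg[, 1],
                            lower = avg[, 2], upper = avg[, 3]),
       by_window = bw)
}

#' Median absolute error of mean time in the highest state
#'
#' Per subject, the absolute difference between the SOP-derived mean time in
#' the highest state and the observed number of windows spent in that state,
#' in 90-day units; summarized by the median and IQR across subjects.
#'
#' @param sop_list named list of per-subject SOP matrices.
#' @param observed data.frame with `patient_id`, `window_index`, `state`
#'   covering the SOP windows.
#' @param state the state of interest (default the highest state).
#' @return List with `median`, `q25`, `q75` and the per-subject `errors`.
#' @export
mean_time_mae <- function(sop_list, observed, state = NULL) {
  s1 <- sop_list[[1]]
  if (is.null(state)) state <- ncol(s1)
  windows <- attr(s1, "windows")
  errs <- vapply(names(sop_list), function(id) {
    s <- sop_list[[id]]
    if (!identical(attr(s, "windows"), windows))
      stop("SOP windows differ between subjects")
    obs <- observed[observed$patient_id == id &
                      observed$window_index %in% windows, , drop = FALSE]
    if (nrow(obs) != length(windows))
      stop("observed windows do not align with SOP windows for ", id)
    abs(sum(unclass(s)[, state]) - sum(obs$state == state))
  }, numeric(1))
  q <- stats::quantile(errs, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  list(median = q[1], q25 = q[2], q75 = q[3], errors = errs)
}
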