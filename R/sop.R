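#' State occupancy probabilities by recursive unconditioning
#'
#' Starting from the observed state at the window before the first prediction
#' window, the first SOP row is the one-step transition distribution; each
#' later row unconditions on the previous state by recursive matrix
#' multiplication: `row_t = row_{t-1} %*% P_t`, where `P_t[s, j]` is the
#' fitted probability of moving from state `s` to state `j` at window `t`
#' for this subject's covariates. Deterministic given the fit.
#'
#' @param fit a [fit_po_markov()] fit (or the equivalent object from
#'   [as_po_fit()] for a known true model).
#' @param covariates one-row data.frame or named list of baseline covariates.
#' @param initial_state observed state at window `min(windows) - 1`.
#' @param windows prediction windows (default `5:20`).
#' @return Object of class `sop_matrix`: a `length(windows) x n_states`
#'   probability matrix with the windows as rownames; rows sum to 1.
#' @export
compute_sops <- function(fit, covariates, initial_state, windows = 5:20) {
  K <- fit$spec$n_states
  if (initial_state < 1 || initial_state > K)
    stop("initial_state outside 1..n_states")
  P <- transition_array(fit, covariates, windows)
  Tn <- length(windows)
  sop <- matrix(0, Tn, K, dimnames = list(windows, paste0("state", 1:K)))
  sop[1, ] <- P[1, initial_state, ]
  if (Tn > 1)
    for (t in 2:Tn) sop[t, ] <- drop(sop[t - 1, ] %*% P[t, , ])
  structure(sop, class = c("sop_matrix", "matrix"), windows = windows,
            initial_state = initial_state)
}

# T x K x K array of one-step transition matrices for one subject:
# P[t, s, j] = P(state j at windows[t] | state s before it)
transition_array <- function(fit, covariates, windows) {
  K <- fit$spec$n_states
  Tn <- length(windows)
  nd <- as.data.frame(covariates)[rep(1, Tn * K), , drop = FALSE]
  grid <- expand.grid(s = seq_len(K), t = windows)
  nd$y_prev <- grid$s
  nd$time <- grid$t
  eta <- predict_eta(fit, nd)
  pr <- po_probs(fit$alpha, eta, K)
  P <- array(0, dim = c(Tn, K, K))
  for (ti in seq_len(Tn))
    P[ti, , ] <- pr[(ti - 1) * K + seq_len(K), , drop = FALSE]
  P
}

#' @export
print.sop_matrix <- function(x, ...) {
  cat("State occupancy probabilities:", nrow(x), "windows x", ncol(x),
      "states (initial state", attr(x, "initial_state"), ")\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Mean time in state from SOPs
#'
#' Sum of a state's occupancy probabilities across the prediction windows,
#' in 90-day units. Over all states the mean times sum exactly to the number
#' of windows.
#'
#' @param sops a [compute_sops()] matrix.
#' @param state state index, or `NULL` for all states.
#' @return Numeric scalar (or named vector over states).
#' @export
mean_time_in_state <- function(sops, state = NULL) {
  tot <- colSums(unclass(sops))
  if (is.null(state)) return(tot)
  if (any(state < 1 | state > ncol(sops))) stop("state out of range")
  tot[state]
}

#' Collapse ordinal states into grouped states
#'
#' Built-in mappings follow the sensitivity analyses: `"four_state"` groups
#' the 10 PDC states as 0-9 / 10-69 / 70-89 / 90-100 percent
#' (`{1}, {2..7}, {8,9}, {10}`), `"three_state"` as 0-9 / 10-89 / 90-100
#' (`{1}, {2..9}, {10}`). A custom mapping is an ordered list of contiguous
#' integer groups partitioning `1..n_states`. State sequences are relabeled;
#' SOP matrices have member-state probabilities summed.
#'
#' @param x integer state vector or a [compute_sops()] matrix.
#' @param mapping `"four_state"`, `"three_state"`, or a list of integer
#'   vectors.
#' @param n_states number of original states (default 10, or taken from the
#'   SOP matrix).
#' @return Relabeled states, or a collapsed `sop_matrix`.
#' @export
collapse_states <- function(x, mapping = "four_state", n_states = 10L) {
  if (inherits(x, "sop_matrix") || is.matrix(x)) n_states <- ncol(x)
  if (is.character(mapping)) {
    mapping <- switch(mapping,
      four_state = list(1L, 2:7, 8:9, 10L),
      three_state = list(1L, 2:9, 10L),
      stop("unknown mapping '", mapping, "'"))
    if (n_states != 10L) stop("built-in mappings assume 10 states")
  }
  flat <- as.integer(unlist(mapping))
  if (!identical(flat, seq_len(n_states)))
    stop("mapping must partition 1..n_states into ordered contiguous groups")
  if (inherits(x, "sop_matrix") || is.matrix(x)) {
    out <- vapply(mapping, function(g)
      rowSums(unclass(x)[, g, drop = FALSE]), numeric(nrow(x)))
    out <- matrix(out, nrow = nrow(x),
                  dimnames = list(rownames(x),
                                  paste0("group", seq_along(mapping))))
    return(structure(out, class = class(x), windows = attr(x, "windows"),
                     initial_state = attr(x, "initial_state")))
  }
  grp <- integer(n_states)
  for (i in seq_along(mapping)) grp[mapping[[i]]] <- i
  if (any(x < 1 | x > n_states)) stop("states out of range")
  grp[x]
}
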