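#' Declarative specification of a Markov transition model
#'
#' A model specification lists the covariate terms, how each enters the
#' linear predictor, which terms interact with time, how the previous state
#' is encoded, and the number of ordinal outcome states. Terms are strings of
#' the form `"transform:variable"` with an optional `"* time"` suffix, e.g.
#' `"rcs4:age"`, `"linear:chads_vasc"`, `"rcs4:days_w3 * time"`. Transforms:
#' `rcs4` (restricted cubic spline, 4 knots, 3 columns) and `linear`.
#'
#' @param terms character vector of term strings (see Details).
#' @param prev_state `"categorical"` (indicator per observed previous state,
#'   reference = highest state) or `"linear"` (single numeric column,
#'   `y_prev - n_states`).
#' @param time `"linear"` (centered window index, default) or `"rcs4"`.
#' @param n_states number of ordinal outcome states (default 10).
#' @param knots optional named list of fixed knot vectors per spline
#'   variable; variables not listed get data-driven quantile knots at fit
#'   time.
#' @param centers optional named numeric of fixed centering constants
#'   (including `"time"`); defaults to training means.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(terms,
                       prev_state = c("categorical", "linear"),
                       time = c("linear", "rcs4"),
                       n_states = 10L,
                       knots = list(),
                       centers = numeric()) {
  prev_state <- match.arg(prev_state)
  time <- match.arg(time)
  parsed <- lapply(terms, parse_term)
  vars <- vapply(parsed, `[[`, character(1), "var")
  if (anyDuplicated(vars))
    stop("duplicate terms for: ", paste(unique(vars[duplicated(vars)]), collapse = ", "))
  structure(
    list(terms = parsed, prev_state = prev_state, time = time,
         n_states = as.integer(n_states), knots = knots, centers = centers),
    class = "model_spec"
  )
}

parse_term <- function(s) {
  s0 <- s
  interact <- grepl("\\*\\s*time\\s*$", s)
  s <- sub("\\*\\s*time\\s*$", "", s)
  s <- trimws(s)
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("cannot parse term '", s0, "'; expected 'transform:variable'")
  transform <- trimws(parts[1])
  if (!transform %in% c("rcs4", "linear"))
    stop("unknown transform '", transform, "' in term '", s0, "'")
  list(var = trimws(parts[2]), transform = transform, interact_time = interact)
}

#' @export
print.model_spec <- function(x, ...) {
  tl <- vapply(x$terms, function(t)
    paste0(t$transform, ":", t$var, if (t$interact_time) " * time" else ""),
    character(1))
  cat("Proportional-odds Markov model specification\n")
  cat("  outcome states:", x$n_states, "\n")
  cat("  terms:", paste(tl, collapse = ", "), "\n")
  cat("  previous state:", x$prev_state, "; time:", x$time, "\n")
  invisible(x)
}

#' The default (final) model specification
#'
#' Restricted cubic splines (4 knots) for age, CHA2DS2-VASc score and the
#' credited days of the four first-year 90-day windows, with the third- and
#' fourth-window splines interacting with time, plus the categorical previous
#' state and a linear time trend.
#'
#' @param n_states number of outcome states.
#' @inheritParams model_spec
#' @return A [model_spec()].
#' @export
final_model_spec <- function(n_states = 10L, knots = list(), centers = numeric()) {
  model_spec(
    c("rcs4:age", "rcs4:chads_vasc", "rcs4:days_w1", "rcs4:days_w2",
      "rcs4:days_w3 * time", "rcs4:days_w4 * time"),
    n_states = n_states, knots = knots, centers = centers
  )
}

#' The model-comparison ladder of candidate specifications
#'
#' Ten candidate models: the basic model (age, score, all four first-year
#' windows), the basic model with time interactions on windows 3-4, a
#' two-window model, models dropping age or the score or both, and models
#' dropping each individual window. All share the previous-state and time
#' encodings.
#'
#' @inheritParams final_model_spec
#' @return Named list of [model_spec()] objects.
#' @export
ladder_specs <- function(n_states = 10L, knots = list(), centers = numeric()) {
  w <- function(i) paste0("rcs4:days_w", i)
  base <- c("rcs4:age", "rcs4:chads_vasc")
  mk <- function(terms) model_spec(terms, n_states = n_states,
                                   knots = knots, centers = centers)
  list(
    basic            = mk(c(base, w(1:4))),
    time_interaction = mk(c(base, w(1:2), paste(w(3:4), "* time"))),
    two_window       = mk(c(base, w(1:2))),
    no_age           = mk(c("rcs4:chads_vasc", w(1:4))),
    no_score         = mk(c("rcs4:age", w(1:4))),
    windows_only     = mk(w(1:4)),
    no_window4       = mk(c(base, w(1:3))),
    no_window3       = mk(c(base, w(c(1, 2, 4)))),
    no_window1       = mk(c(base, w(2:4))),
    no_window2       = mk(c(base, w(c(1, 3, 4))))
  )
}

term_cols <- function(term, x, knots) {
  if (term$transform == "rcs4") {
    b <- rcs_basis(x, knots)
    colnames(b) <- paste0(term$var, colnames(b))
    b
  } else {
    matrix(x, ncol = 1, dimnames = list(NULL, term$var))
  }
}

#' Build the design matrix for a transition table
#'
#' Assembles the model matrix from a [model_spec()] and a transition table:
#' spline/linear main-effect blocks, column-wise products of interacting
#' blocks with centered time, the previous-state encoding and the time term.
#' Knots default to quantile placement on the training data and centering
#' constants to training means; both can be frozen (for prediction, or for
#' simulation studies where the truth is defined on fixed knots).
#'
#' @param spec a [model_spec()].
#' @param data data.frame with one row per transition; must contain every
#'   term variable plus `y_prev` and `time`.
#' @param knots,centers optional overrides (same format as in
#'   [model_spec()]); precedence: argument > spec > data-driven.
#' @param prev_levels optional integer vector of previous-state levels seen
#'   in training (used when building prediction rows so the column layout
#'   matches the fit).
#' @return List of class `design_matrix` with elements `X` (numeric matrix),
#'   `knots`, `centers`, `prev_levels`, `spec`.
#' @export
build_design <- function(spec, data, knots = NULL, centers = NULL,
                         prev_levels = NULL) {
  vars <- vapply(spec$terms, `[[`, character(1), "var")
  need <- c(vars, "y_prev", "time")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[need])) stop("missing values in model variables")

  # resolve knots and centers with argument > spec > data-driven precedence
  kn <- spec$knots
  if (!is.null(knots)) kn[names(knots)] <- knots
  cn <- spec$centers
  if (!is.null(centers) && length(centers)) cn[names(centers)] <- centers
  spline_vars <- vars[vapply(spec$terms, function(t) t$transform == "rcs4",
                             logical(1))]
  if (spec$time == "rcs4") spline_vars <- c(spline_vars, "time")
  for (v in spline_vars)
    if (is.null(kn[[v]])) kn[[v]] <- choose_knots(data[[v]], v)
  for (v in c(vars, "time"))
    if (is.null(cn[v]) || is.na(cn[v])) cn[v] <- mean(data[[v]])

  time_c <- data$time - cn[["time"]]

  blocks <- list()
  for (term in spec$terms) {
    b <- term_cols(term, data[[term$var]], kn[[term$var]])
    blocks[[length(blocks) + 1L]] <- b
    if (term$interact_time) {
      bi <- b * time_c
      colnames(bi) <- paste(colnames(b), "* time")
      blocks[[length(blocks) + 1L]] <- bi
    }
  }

  # previous-state encoding
  if (spec$prev_state == "categorical") {
    if (is.null(prev_levels)) prev_levels <- sort(unique(data$y_prev))
    ref <- max(prev_levels)
    yp <- snap_to_levels(data$y_prev, prev_levels)
    nonref <- setdiff(prev_levels, ref)
    if (length(nonref)) {
      ind <- vapply(nonref, function(l) as.numeric(yp == l),
                    numeric(nrow(data)))
      ind <- matrix(ind, nrow = nrow(data))
      colnames(ind) <- paste0("prev=", nonref)
      blocks[[length(blocks) + 1L]] <- ind
    }
  } else {
    blocks[[length(blocks) + 1L]] <-
      matrix(data$y_prev - spec$n_states, ncol = 1,
             dimnames = list(NULL, "prev"))
    prev_levels <- seq_len(spec$n_states)
  }

  # time main effect
  if (spec$time == "rcs4") {
    bt <- rcs_basis(time_c, kn[["time"]] - cn[["time"]])
    colnames(bt) <- paste0("time", colnames(bt))
    blocks[[length(blocks) + 1L]] <- bt
  } else {
    blocks[[length(blocks) + 1L]] <-
      matrix(time_c, ncol = 1, dimnames = list(NULL, "time"))
  }

  X <- do.call(cbind, blocks)
  structure(list(X = X, knots = kn, centers = cn,
                 prev_levels = prev_levels, spec = spec),
            class = "design_matrix")
}

# Map previous-state values onto the levels observed in training, snapping
# unobserved levels to the nearest observed one (logged once).
snap_to_levels <- function(y_prev, levels) {
  out <- y_prev
  unseen <- setdiff(unique(y_prev), levels)
  if (length(unseen)) {
    message("previous-state level(s) ", paste(unseen, collapse = ", "),
            " not seen in training; merged with nearest observed level")
    for (u in unseen) out[y_prev == u] <- levels[which.min(abs(levels - u))]
  }
  out
}
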