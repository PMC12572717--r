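#' Restricted cubic spline basis
#'
#' Evaluates the restricted (natural) cubic spline basis with `k` knots: a
#' linear column plus `k - 2` truncated-power columns constrained so that any
#' linear combination is linear beyond the boundary knots. The nonlinear
#' columns use the conventional normalization by the squared knot span,
#' keeping them on roughly the scale of `x`.
#'
#' For knots `t1 < ... < tk` the j-th nonlinear column (j = 1..k-2) is
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'       + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#'
#' @param x numeric vector.
#' @param knots strictly increasing numeric vector (length >= 3; 4 by
#'   convention here).
#' @return Matrix with `length(knots) - 1` columns; column 1 is `x` itself.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 3L) stop("need at least 3 knots")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  k <- length(knots)
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  norm <- (tk - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                      pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                      pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- vapply(seq_len(k - 1L) - 1L,
                          function(p) paste(rep("'", p), collapse = ""),
                          character(1))
  out
}

#' Default knot placement for a 4-knot restricted cubic spline
#'
#' Knots at the 0.05, 0.35, 0.65 and 0.95 quantiles (type-7, linear
#' interpolation), the conventional default for four knots. Deterministic for
#' a fixed input.
#'
#' @param x numeric vector with at least 20 distinct values.
#' @return Numeric vector of 4 strictly increasing knots.
#' @export
default_knots <- function(x) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 20L)
    stop("need at least 20 distinct values to place knots by quantile")
  kn <- unname(stats::quantile(x, c(0.05, 0.35, 0.65, 0.95), type = 7))
  if (length(unique(kn)) < 4L)
    stop("quantile knots are not distinct; supply knots explicitly")
  kn
}

# Knot selection with a fallback for heavily tied variables (e.g. days
# covered massed at 90): if the standard quantile knots tie, fall back to
# quantiles of the distinct values.
choose_knots <- function(x, var = "x") {
  kn <- tryCatch(default_knots(x), error = function(e) NULL)
  if (!is.null(kn)) return(kn)
  ux <- unique(x[!is.na(x)])
  if (length(ux) < 4L)
    stop("cannot place 4 distinct knots for '", var, "'")
  kn <- unname(stats::quantile(sort(ux), c(0.05, 0.35, 0.65, 0.95), type = 7))
  if (length(unique(kn)) < 4L)
    stop("cannot place 4 distinct knots for '", var, "'")
  warning("tied quantile knots for '", var,
          "'; using quantiles of distinct values instead", call. = FALSE)
  kn
}
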