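#' Serialize a fitted model to JSON
#'
#' Writes everything needed to reproduce predictions bit-for-bit: the model
#' specification, knots, centering constants, previous-state levels,
#' intercepts, coefficients, covariance and log-likelihood. Numbers are
#' written at full precision.
#'
#' @param fit a [fit_po_markov()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  spec <- fit$spec
  obj <- list(
    spec = list(
      terms = vapply(spec$terms, function(t)
        paste0(t$transform, ":", t$var,
               if (t$interact_time) " * time" else ""), character(1)),
      prev_state = spec$prev_state,
      time = spec$time,
      n_states = spec$n_states
    ),
    knots = fit$knots,
    centers = as.list(fit$centers),
    prev_levels = fit$prev_levels,
    alpha = as.list(fit$alpha),
    beta = as.list(fit$beta),
    vcov = if (is.null(fit$vcov)) NULL else unclass(fit$vcov),
    loglik = fit$loglik,
    n_obs = fit$n_obs,
    n_params = fit$n_params,
    converged = fit$converged,
    var_ranges = fit$var_ranges
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path file written by [write_fit_json()].
#' @return A `po_fit`.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(obj$spec$terms, prev_state = obj$spec$prev_state,
                     time = obj$spec$time, n_states = obj$spec$n_states)
  vcov <- obj$vcov
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    dimnames(vcov) <- list(c(names(obj$alpha), names(obj$beta)),
                           c(names(obj$alpha), names(obj$beta)))
  }
  structure(list(
    alpha = unlist(obj$alpha), beta = unlist(obj$beta),
    loglik = obj$loglik, vcov = vcov, n_obs = obj$n_obs,
    n_params = obj$n_params, converged = obj$converged, spec = spec,
    knots = obj$knots, centers = unlist(obj$centers),
    prev_levels = obj$prev_levels,
    var_ranges = obj$var_ranges
  ), class = "po_fit")
}
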