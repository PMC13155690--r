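# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted observer model
#'
#' @param x An `observer_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `lower`, `upper`, `role`.
#' @export
tidy.observer_fit <- function(x, ...) {
  tibble::tibble(
    term = x$spec$term,
    estimate = unname(x$params[x$spec$term]),
    lower = x$spec$lower,
    upper = x$spec$upper,
    role = x$spec$role
  )
}

#' One-row summary of a fitted observer model
#'
#' @param x An `observer_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `task_scope`, `nll`, `aic`, `bic`,
#'   `n_params`, `n_trials`, `n_restarts`.
#' @export
glance.observer_fit <- function(x, ...) {
  ic <- aic_bic(x$nll, length(x$params), x$n_trials)
  tibble::tibble(
    model = x$model_name, task_scope = x$task_scope, nll = x$nll,
    aic = ic$aic, bic = ic$bic, n_params = length(x$params),
    n_trials = x$n_trials, n_restarts = nrow(x$restarts)
  )
}

#' Tidy a parameter-recovery result
#'
#' @param x A `recovery_scatter`.
#' @param ... Unused.
#' @return The tibble of (true, recovered) pairs.
#' @export
tidy.recovery_scatter <- function(x, ...) {
  x$pairs
}

#' Per-parameter recovery summary
#'
#' @param x A `recovery_scatter`.
#' @param ... Unused.
#' @return The tibble of per-term rank correlations and errors.
#' @export
glance.recovery_scatter <- function(x, ...) {
  x$summary
}
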