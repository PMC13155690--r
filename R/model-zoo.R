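# Model registry accounting and AIC/BIC group comparison.

#' Build a model skeleton from a registry name
#'
#' Returns the model's parameter specification together with an `assemble`
#' closure producing an [observer_model()] from a named parameter vector. The
#' free-parameter inventory is derived from the name alone (bisensory scope
#' adds `p_same`, `beta_v`, `beta_a`; a recalibration suffix fixes `rho_a` at
#' 1 or 4/3; lifted models freeze the 35 shape parameters).
#'
#' @param model_name Registry model name.
#' @param task_scope `"unisensory"` or `"all"`.
#' @return A list with `model_name`, `task_scope`, `spec`, `n_free`,
#'   `n_frozen`, and `assemble(params, grids, frozen)`.
#' @export
#' @examples
#' build_model("Exp-GaussianLaplace-PM", "all")$n_free # 17
build_model <- function(model_name, task_scope = c("unisensory", "all")) {
  task_scope <- match.arg(task_scope)
  spec <- parameter_spec(model_name, task_scope)
  list(
    model_name = model_name, task_scope = task_scope, spec = spec,
    n_free = nrow(spec), n_frozen = attr(spec, "n_frozen"),
    assemble = function(params, grids = grid_spec(), frozen = NULL) {
      assemble_observer(model_name, params, task_scope, grids, frozen)
    }
  )
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2 NLL + 2 k` and `BIC = 2 NLL + ln(N) k` for `k` free parameters and
#' `N` trials.
#'
#' @param nll Negative log likelihood(s).
#' @param n_params Free-parameter count(s).
#' @param n_trials Trial count(s), positive.
#' @return A tibble with columns `aic` and `bic`.
#' @export
#' @examples
#' aic_bic(100, 5, 3000)
aic_bic <- function(nll, n_params, n_trials) {
  stopifnot(all(n_trials > 0))
  tibble::tibble(
    aic = 2 * nll + 2 * n_params,
    bic = 2 * nll + log(n_trials) * n_params
  )
}

#' Complexity accounting for lifted fits
#'
#' A lifted fit optimizes 9 context parameters but inherits 35 frozen shape
#' parameters (12 + 12 noise values, 11 prior values) from the upstream
#' unisensory fit. `exclude_frozen` counts only the free parameters (the naive
#' score); `include_frozen` adds the frozen shapes to `n_params`, correcting
#' for the double-dipping of shapes already fitted on unisensory data.
#'
#' @param fit An `observer_fit` from [lift_semiparametric()].
#' @param mode `"exclude_frozen"` or `"include_frozen"`.
#' @return A tibble with `aic`, `bic` and the `n_params` used.
#' @export
lifted_complexity <- function(fit, mode = c("exclude_frozen", "include_frozen")) {
  mode <- match.arg(mode)
  if (!inherits(fit, "observer_fit") || !parse_model_name(fit$model_name)$lifted) {
    abort("`fit` must be a lifted-semiparametric fit.")
  }
  n_params <- length(fit$params) +
    if (mode == "include_frozen") attr(fit$spec, "n_frozen") else 0L
  dplyr::mutate(aic_bic(fit$nll, n_params, fit$n_trials), n_params = n_params)
}

#' Group-level model comparison table
#'
#' From per-participant, per-model fit summaries, computes group-summed NLL,
#' AIC and BIC, differences to the best model per metric, and bootstrap 95%
#' intervals of each difference obtained by resampling participants with
#' replacement.
#'
#' @param fits A tibble with columns `participant`, `model`, `nll`, `n_params`,
#'   `n_trials` (one row per participant x model; `n_trials` is the
#'   per-participant count of the fitted task scope), or a list of
#'   `observer_fit` objects carrying a `participant` attribute.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A `comparison_table` object: tibble with one row per model and
#'   columns `model`, `nll`, `aic`, `bic`, `delta_nll`, `delta_aic`,
#'   `delta_bic` and the bootstrap interval columns `*_lo`, `*_hi`.
#' @export
group_comparison <- function(fits, n_boot = 10000, seed = 1) {
  fits <- as_fit_table(fits)
  cells <- dplyr::distinct(fits[, c("participant", "model")])
  if (nrow(cells) != dplyr::n_distinct(fits$participant) *
        dplyr::n_distinct(fits$model) || nrow(cells) != nrow(fits)) {
    abort("Every model must be fitted exactly once for every participant.")
  }
  per <- dplyr::mutate(fits, aic_bic(.data$nll, .data$n_params, .data$n_trials))
  metrics <- c("nll", "aic", "bic")

  participants <- sort(unique(per$participant))
  models <- sort(unique(per$model))
  cube <- lapply(metrics, function(m) {
    mat <- matrix(0, length(participants), length(models),
      dimnames = list(participants, models))
    mat[cbind(match(per$participant, participants), match(per$model, models))] <-
      per[[m]]
    mat
  })
  names(cube) <- metrics

  out <- tibble::tibble(model = models)
  set.seed(derive_seed(seed, "bootstrap"))
  idx_boot <- matrix(sample.int(length(participants),
    length(participants) * n_boot, replace = TRUE), nrow = n_boot)
  for (m in metrics) {
    sums <- colSums(cube[[m]])
    best <- which.min(sums)
    delta <- sums - sums[best]
    boot_delta <- t(apply(idx_boot, 1, function(idx) {
      s <- colSums(cube[[m]][idx, , drop = FALSE])
      s - s[best]
    }))
    ci <- apply(boot_delta, 2, quantile, probs = c(0.025, 0.975))
    out[[m]] <- unname(sums)
    out[[paste0("delta_", m)]] <- unname(delta)
    out[[paste0("delta_", m, "_lo")]] <- unname(ci[1, ])
    out[[paste0("delta_", m, "_hi")]] <- unname(ci[2, ])
  }
  class(out) <- c("comparison_table", class(out))
  out
}

as_fit_table <- function(fits) {
  if (is.data.frame(fits)) {
    needed <- c("participant", "model", "nll", "n_params", "n_trials")
    if (!all(needed %in% names(fits))) {
      abort(paste0("Fit table needs columns: ", paste(needed, collapse = ", ")))
    }
    return(tibble::as_tibble(fits))
  }
  purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      participant = attr(f, "participant") %||% NA,
      model = f$model_name, nll = f$nll, n_params = length(f$params),
      n_trials = f$n_trials
    )
  })
}

#' Per-participant best-model aggregation
#'
#' For each participant, selects the model minimizing the chosen metric and
#' sums the selected values across participants — selection is done per metric,
#' so the NLL-best, AIC-best and BIC-best sets may differ.
#'
#' @inheritParams group_comparison
#' @return A tibble with one row per metric: `metric`, `total`, and the
#'   per-participant selections nested in `selection`.
#' @export
parametric_best <- function(fits) {
  fits <- as_fit_table(fits)
  if (nrow(fits) == 0) abort("Empty fit table.")
  per <- dplyr::mutate(fits, aic_bic(.data$nll, .data$n_params, .data$n_trials))
  purrr::map_dfr(c("nll", "aic", "bic"), function(m) {
    sel <- per |>
      dplyr::group_by(.data$participant) |>
      dplyr::slice_min(.data[[m]], n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    tibble::tibble(
      metric = m, total = sum(sel[[m]]),
      selection = list(sel[, c("participant", "model", m)])
    )
  })
}
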