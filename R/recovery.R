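# Model- and parameter-recovery harnesses: simulate groups from candidate
# models, refit, and assess identifiability.

#' Default quadrature tier of the recovery harnesses
#'
#' The recovery harnesses run many maximum-likelihood fits; their default
#' grids trade a negligible likelihood bias (well below one NLL unit per
#' thousand trials against the full-resolution grids) for several-fold faster
#' objective evaluations. Pass `grids = grid_spec()` for full resolution.
#'
#' @return A [grid_spec()].
#' @export
recovery_grids <- function() {
  grid_spec(s_points = 241, x_points = 61, shat_spacing = 0.5,
    x_points_2d = 41, field_spacing = 0.5)
}

#' Model recovery: can AIC/BIC identify the generating model?
#'
#' For each candidate model, simulates a group of synthetic participants from
#' that model, fits every candidate to every simulated participant, sums NLL /
#' AIC / BIC over participants, and differences each fitted model against the
#' generating (diagonal) model. Successful recovery means every off-diagonal
#' AIC/BIC difference is positive.
#'
#' @param candidates Character vector of registry model names.
#' @param design An [experiment_design()].
#' @param seed Master seed; simulation and fitting substreams are derived from
#'   it.
#' @param task_scope `"unisensory"` or `"all"`.
#' @param n_starts Restart budget per fit.
#' @param params_source Optional list (named by candidate) of per-participant
#'   parameter lists; defaults to draws from the synthetic ranges.
#' @param grids A [grid_spec()] shared by simulation and fitting.
#' @param optimizer,control Passed to [fit_mle()].
#' @return A `recovery_matrix` object: tibble with one row per
#'   (generator, fitted) pair and columns `nll`, `aic`, `bic`,
#'   `delta_nll`, `delta_aic`, `delta_bic`; fit failures are recorded in the
#'   `error` column, never imputed.
#' @export
run_model_recovery <- function(candidates, design = experiment_design(),
                               seed = 1, task_scope = c("unisensory", "all"),
                               n_starts = 2, params_source = NULL,
                               grids = recovery_grids(), optimizer = NULL,
                               control = list()) {
  task_scope <- match.arg(task_scope)
  if (length(candidates) == 0) abort("Empty candidate set.")
  rows <- list()
  for (gen in candidates) {
    group <- make_simulated_group(gen,
      params_per_participant = params_source[[gen]],
      design = design, seed = derive_seed(seed, "group", gen),
      task_scope = task_scope, grids = grids)
    for (cand in candidates) {
      fits <- fit_group(group$trials, cand, task_scope, n_starts,
        seed = derive_seed(seed, "fit", gen, cand), grids, optimizer, control)
      failed <- any(!is.na(fits$error))
      sum_of <- function(f) {
        if (failed) NA_real_ else sum(purrr::map_dbl(fits$fit, f))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        generator = gen, fitted = cand,
        n_params = nrow(parameter_spec(cand, task_scope)),
        nll = sum_of(~ .x$nll),
        aic = sum_of(~ aic_bic(.x$nll, length(.x$params), .x$n_trials)$aic),
        bic = sum_of(~ aic_bic(.x$nll, length(.x$params), .x$n_trials)$bic),
        error = paste(stats::na.omit(fits$error), collapse = "; ")
      )
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$generator) |>
    dplyr::mutate(
      delta_nll = .data$nll - .data$nll[.data$fitted == .data$generator],
      delta_aic = .data$aic - .data$aic[.data$fitted == .data$generator],
      delta_bic = .data$bic - .data$bic[.data$fitted == .data$generator]
    ) |>
    dplyr::ungroup()
  structure(out, class = c("recovery_matrix", class(out)),
    seed = seed, design = design, n_starts = n_starts)
}

fit_group <- function(trials, model_name, task_scope, n_starts, seed, grids,
                      optimizer, control) {
  participants <- sort(unique(trials$participant))
  res <- purrr::map(participants, function(p) {
    dat <- trials[trials$participant == p, , drop = FALSE]
    tryCatch(
      list(fit = fit_mle(dat, model_name, n_starts = n_starts,
        seed = derive_seed(seed, "participant", p), optimizer = optimizer,
        grids = grids, control = control), error = NA_character_),
      error = function(e) list(fit = NULL, error = conditionMessage(e))
    )
  })
  list(fit = purrr::map(res, "fit"),
    error = purrr::map_chr(res, "error"))
}

#' Parameter recovery: true versus refitted parameter values
#'
#' Simulates a group from one model with known per-participant parameters,
#' refits the same model, and pairs true with recovered values per parameter.
#' Summaries report the Spearman rank correlation and median absolute relative
#' error across simulated participants.
#'
#' @inheritParams run_model_recovery
#' @param model_name Generating (and fitted) registry model name.
#' @param true_params Optional list of per-participant named parameter vectors;
#'   defaults to draws from the synthetic ranges.
#' @return A `recovery_scatter` object: list with `pairs` (tibble of
#'   `participant`, `term`, `true`, `recovered`), `summary` (per-term rank
#'   correlation and median absolute relative error), and `fits`.
#' @export
run_parameter_recovery <- function(model_name, design = experiment_design(),
                                   seed = 1, task_scope = c("unisensory", "all"),
                                   n_starts = 2, true_params = NULL,
                                   grids = recovery_grids(), optimizer = NULL,
                                   control = list()) {
  task_scope <- match.arg(task_scope)
  group <- make_simulated_group(model_name, true_params, design,
    seed = derive_seed(seed, "group"), task_scope = task_scope, grids = grids)
  fits <- fit_group(group$trials, model_name, task_scope, n_starts,
    seed = derive_seed(seed, "fit"), grids, optimizer, control)
  failed <- which(!is.na(fits$error))
  if (length(failed) > 0) {
    abort(paste0("Fit failure for participant(s) ",
      paste(failed, collapse = ", "), ": ",
      paste(unique(stats::na.omit(fits$error)), collapse = "; ")))
  }
  pairs <- purrr::map_dfr(seq_along(fits$fit), function(p) {
    tp <- group$params[[p]]
    rp <- fits$fit[[p]]$params
    tibble::tibble(participant = p, term = names(rp),
      true = unname(tp[names(rp)]), recovered = unname(rp))
  })
  summary <- pairs |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      rank_correlation = suppressWarnings(
        stats::cor(.data$true, .data$recovered, method = "spearman")),
      median_abs_rel_error = median(
        abs(.data$recovered - .data$true) / pmax(abs(.data$true), 1e-12)),
      .groups = "drop"
    )
  structure(
    list(pairs = pairs, summary = summary, fits = fits$fit,
      model_name = model_name, seed = seed, design = design,
      true_params = group$params),
    class = "recovery_scatter"
  )
}

#' @export
print.recovery_scatter <- function(x, ...) {
  cat("<recovery_scatter>", x$model_name, "\n")
  print(x$summary, n = Inf)
  invisible(x)
}
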