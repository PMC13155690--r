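# Sampling-path simulator of observer responses. Deliberately independent of
# the grid engine's cached tables and fields: measurements are drawn per trial
# and estimates are computed by direct posterior-mean quadrature at the sampled
# measurement, so the simulator and the likelihood engine can serve as mutual
# oracles.

#' Simulate observer responses for a stimulus table
#'
#' For each trial: draw the noisy measurement(s) from the generative
#' measurement distributions; recalibrate the auditory measurement by `rho_a`;
#' compute the strategy-specific estimate or categorical choice by explicit
#' sampling (PM draws the causal hypothesis, MS/MA are deterministic given the
#' measurements); add Gaussian motor noise; and with probability `lambda`
#' replace the response by a uniform draw over the response range
#' (localization) or a fair category draw (BC).
#'
#' @param trials Trial tibble with stimuli (responses are overwritten).
#' @param observer An [observer_model()].
#' @param seed Integer seed; the run is bit-reproducible.
#' @return The trial tibble with `response_loc` / `response_cat` filled in.
#' @export
#' @examples
#' obs <- observer_model(prior_single_gaussian(10), noise_const(2, "V"),
#'   noise_const(4, "A"), context = context_params(sigma_motor = 0.5))
#' trials <- sample_experiment(experiment_design(n_participants = 1,
#'   trials_per_task = c(UV = 10, UA = 10, B = 10, BC = 10)), seed = 1)
#' simulate_responses(trials, obs, seed = 2)
simulate_responses <- function(trials, observer, seed) {
  validate_trials(trials)
  set.seed(derive_seed(seed, "simulate"))
  ctx <- observer$context
  s_grid <- observer$s_grid
  pw <- observer$prior_w
  out_loc <- rep(NA_real_, nrow(trials))
  out_cat <- rep(NA_integer_, nrow(trials))

  # order of random draws is fixed by (task, reliability) group, seeded once
  for (task in TASKS) {
    rels <- if (task == "UA") NA_character_ else RELIABILITIES
    for (rel in rels) {
      rows <- which(trials$task == task &
        (is.na(rel) | (!is.na(trials$reliability) & trials$reliability == rel)))
      if (length(rows) == 0) next
      n <- length(rows)
      rel_arg <- if (is.na(rel)) NULL else rel

      if (task %in% c("UV", "UA")) {
        modality <- if (task == "UV") "V" else "A"
        s <- if (task == "UV") trials$s_v[rows] else trials$s_a[rows]
        sig <- sigma_at(observer, modality, s,
          if (modality == "V") rel_arg else NULL, bisensory = FALSE)
        x <- rnorm(n, s, sig)
        m <- if (modality == "A") apply_recalibration(x, ctx$rho_a) else x
        sig_grid <- sigma_on_grid(observer, modality,
          if (modality == "V") rel_arg else NULL, bisensory = FALSE)
        shat <- post_mean_direct(m, s_grid, sig_grid, pw)
        resp <- shat + rnorm(n, 0, ctx$sigma_motor)
        lapse <- runif(n) < ctx$lambda
        resp[lapse] <- runif(sum(lapse), -RANGE_HALF, RANGE_HALF)
        out_loc[rows] <- resp
      } else {
        sig_v <- sigma_at(observer, "V", trials$s_v[rows], rel_arg, bisensory = TRUE)
        sig_a <- sigma_at(observer, "A", trials$s_a[rows], NULL, bisensory = TRUE)
        x_v <- rnorm(n, trials$s_v[rows], sig_v)
        m_a <- apply_recalibration(rnorm(n, trials$s_a[rows], sig_a), ctx$rho_a)
        sv_grid <- sigma_on_grid(observer, "V", rel_arg, bisensory = TRUE)
        sa_grid <- sigma_on_grid(observer, "A", NULL, bisensory = TRUE)
        bis <- bis_posterior_direct(x_v, m_a, s_grid, sv_grid, sa_grid, pw,
          ctx$p_same)

        if (task == "BC") {
          cat_resp <- if (observer$strategy == "PM") {
            ifelse(runif(n) < bis$pc1, 1L, 2L)
          } else {
            ifelse(bis$pc1 >= 0.5, 1L, 2L)
          }
          lapse <- runif(n) < ctx$lambda
          cat_resp[lapse] <- sample(c(1L, 2L), sum(lapse), replace = TRUE)
          out_cat[rows] <- cat_resp
        } else {
          tgt_mat_means <- if (task == "BV") bis$shat2_v else bis$shat2_a
          est <- switch(observer$strategy,
            MS = ifelse(bis$pc1 >= 0.5, bis$shat1, tgt_mat_means),
            MA = bis$pc1 * bis$shat1 + (1 - bis$pc1) * tgt_mat_means,
            PM = ifelse(runif(n) < bis$pc1, bis$shat1, tgt_mat_means)
          )
          resp <- est + rnorm(n, 0, ctx$sigma_motor)
          lapse <- runif(n) < ctx$lambda
          resp[lapse] <- runif(sum(lapse), -RANGE_HALF, RANGE_HALF)
          out_loc[rows] <- resp
        }
      }
    }
  }
  trials$response_loc <- out_loc
  trials$response_cat <- out_cat
  trials
}

# Direct (per-measurement, chunked) causal posterior and posterior means for
# sampled measurement pairs.
bis_posterior_direct <- function(x_v, m_a, s_grid, sv, sa, pw, p_same,
                                 chunk = 2048L) {
  n <- length(x_v)
  pc1 <- shat1 <- shat2_v <- shat2_a <- numeric(n)
  pws <- pw * s_grid
  for (idx in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    v_mat <- lik_matrix(s_grid, sv, x_v[idx])
    a_mat <- lik_matrix(s_grid, sa, m_a[idx])
    joint <- v_mat * a_mat
    l1 <- as.vector(crossprod(joint, pw))
    mv <- as.vector(crossprod(v_mat, pw))
    ma <- as.vector(crossprod(a_mat, pw))
    den <- p_same * l1 + (1 - p_same) * mv * ma
    pc1[idx] <- ifelse(den > 0, p_same * l1 / den, p_same)
    shat1[idx] <- ifelse(l1 > 0, as.vector(crossprod(joint, pws)) / l1, 0)
    shat2_v[idx] <- as.vector(crossprod(v_mat, pws)) / mv
    shat2_a[idx] <- as.vector(crossprod(a_mat, pws)) / ma
  }
  list(pc1 = pc1, shat1 = shat1, shat2_v = shat2_v, shat2_a = shat2_a)
}

#' Simulate a full group of synthetic participants
#'
#' Samples the experiment for each participant, builds the generating observer
#' from per-participant parameter vectors, and simulates all responses.
#' Provenance (model name, parameters, seed, design) is embedded in the result.
#'
#' @param model_name Registry name of the generating model (see
#'   [build_model()]).
#' @param params_per_participant A list of named parameter vectors (one per
#'   participant), or `NULL` to draw each participant's parameters from the
#'   package's synthetic parameter ranges (see [synthetic_parameter_ranges()]).
#' @param design An [experiment_design()].
#' @param seed Integer master seed.
#' @param task_scope `"unisensory"` or `"all"`.
#' @param grids A [grid_spec()] used by the generating observers.
#' @return A `simulated_group` object: list with `trials`, `params`,
#'   `model_name`, `design`, `seed`.
#' @export
make_simulated_group <- function(model_name, params_per_participant = NULL,
                                 design = experiment_design(), seed = 1,
                                 task_scope = c("all", "unisensory"),
                                 grids = grid_spec()) {
  task_scope <- match.arg(task_scope)
  spec <- parameter_spec(model_name, task_scope)
  n_p <- design$n_participants
  if (is.null(params_per_participant)) {
    params_per_participant <- lapply(seq_len(n_p), function(p) {
      draw_synthetic_params(spec, derive_seed(seed, "params", p))
    })
  }
  if (length(params_per_participant) != n_p) {
    abort("Need one parameter vector per participant.")
  }
  stimuli <- sample_experiment(design, seed = derive_seed(seed, "stimuli"))
  if (task_scope == "unisensory") {
    stimuli <- dplyr::filter(stimuli, .data$task %in% c("UV", "UA"))
  }
  responded <- purrr::map_dfr(seq_len(n_p), function(p) {
    params <- check_params(spec, params_per_participant[[p]])
    obs <- assemble_observer(model_name, params, task_scope, grids)
    simulate_responses(dplyr::filter(stimuli, .data$participant == p), obs,
      seed = derive_seed(seed, "responses", p))
  })
  structure(
    list(trials = responded, params = params_per_participant,
      model_name = model_name, task_scope = task_scope, design = design,
      seed = seed),
    class = "simulated_group"
  )
}

#' @export
print.simulated_group <- function(x, ...) {
  cat("<simulated_group>", x$model_name, sprintf("(%s tasks)\n", x$task_scope))
  cat(" ", length(x$params), "participants,", nrow(x$trials), "trials, seed",
    x$seed, "\n")
  invisible(x)
}
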