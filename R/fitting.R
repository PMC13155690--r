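# Maximum-likelihood fitting: NLL objective, multi-start optimization,
# and lifting of semiparametric unisensory fits to all tasks.

#' Summed negative log likelihood of a trial table
#'
#' Sums `-log` of the per-trial response probability/density from the
#' likelihood engine. Per-trial values are floored at a tiny positive constant
#' before the log so the objective stays finite under pathological parameters.
#'
#' @param params Named vector of the model's free parameters.
#' @param model_name Registry model name.
#' @param data Responded trial tibble.
#' @param tasks Optional subset of tasks to restrict the data to.
#' @param grids A [grid_spec()].
#' @param frozen Frozen shape parameters for lifted models (see
#'   [assemble_observer()]).
#' @return The scalar NLL.
#' @export
negative_log_likelihood <- function(params, model_name, data, tasks = NULL,
                                    grids = grid_spec(), frozen = NULL) {
  if (!is.null(tasks)) data <- data[data$task %in% tasks, , drop = FALSE]
  if (nrow(data) == 0) abort("No trials left after task restriction.")
  task_scope <- if (!parse_model_name(model_name)$lifted &&
      all(data$task %in% c("UV", "UA"))) "unisensory" else "all"
  observer <- assemble_observer(model_name, params, task_scope, grids, frozen)
  lik <- trial_likelihood(observer, data)
  -sum(log(pmax(lik, DENSITY_FLOOR)))
}

# --- optimizers (pluggable contract) -----------------------------------------
# An optimizer takes (fn, start, control) with fn defined on the unconstrained
# transformed space, and returns list(par, value, counts, convergence).

optimizer_lbfgsb <- function(fn, start, control = list()) {
  res <- optim(start, fn, method = "L-BFGS-B",
    control = list(maxit = control$maxit %||% 500,
      factr = control$factr %||% 1e10))
  list(par = res$par, value = res$value, counts = sum(res$counts, na.rm = TRUE),
    convergence = res$convergence)
}

optimizer_neldermead <- function(fn, start, control = list()) {
  res <- optim(start, fn, method = "Nelder-Mead",
    control = list(maxit = control$maxit %||% 2000,
      reltol = control$reltol %||% 1e-7))
  list(par = res$par, value = res$value, counts = res$counts[[1]],
    convergence = res$convergence)
}

# Minimal (mu/mu_w, lambda)-CMA-ES for the high-dimensional semiparametric
# fits; standard rank-mu update with cumulative step-size adaptation.
optimizer_cmaes <- function(fn, start, control = list()) {
  n <- length(start)
  lambda <- control$popsize %||% (4 + floor(3 * log(n)))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- start
  sigma <- control$sigma0 %||% 1.5
  pc <- ps <- numeric(n)
  C <- diag(n)
  best_x <- m
  best_f <- fn(m)
  n_eval <- 1
  max_eval <- control$maxeval %||% (3000 * n)
  iter <- 0
  while (n_eval < max_eval) {
    iter <- iter + 1
    ev <- eigen(C, symmetric = TRUE)
    d <- sqrt(pmax(ev$values, 1e-14))
    B <- ev$vectors
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (d * Z)
    X <- m + sigma * Y
    f <- apply(X, 2, fn)
    n_eval <- n_eval + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- X[, ord[1]]
    }
    y_w <- Y[, ord[seq_len(mu)], drop = FALSE] %*% w
    m <- m + sigma * as.vector(y_w)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mu_eff) *
      as.vector(B %*% ((1 / d) * crossprod(B, y_w)))
    hsig <- as.numeric(sqrt(sum(ps^2)) /
        sqrt(1 - (1 - cs)^(2 * iter)) / chi_n < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * as.vector(y_w)
    artmp <- Y[, ord[seq_len(mu)], drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chi_n - 1))
    if (sigma < 1e-8 || (iter > 20 && diff(range(f)) < 1e-9)) break
  }
  list(par = best_x, value = best_f, counts = n_eval, convergence = 0L)
}

select_optimizer <- function(optimizer, n_free) {
  if (is.function(optimizer)) return(list(fun = optimizer, name = "custom"))
  if (is.null(optimizer)) {
    optimizer <- if (n_free > 20) "cmaes" else "lbfgsb"
  }
  fun <- switch(optimizer,
    lbfgsb = optimizer_lbfgsb,
    neldermead = optimizer_neldermead,
    cmaes = optimizer_cmaes,
    abort(sprintf("Unknown optimizer '%s'.", optimizer)))
  list(fun = fun, name = optimizer)
}

# Stratified (Latin hypercube) start points in raw parameter space.
# Initializations are randomized uniformly within reasonable ranges — the
# package's plausible degree-scale ranges where defined (see
# synthetic_parameter_ranges()), otherwise the central 80% of the bounds.
latin_hypercube_starts <- function(spec, n) {
  k <- nrow(spec)
  u <- vapply(seq_len(k), function(j) (sample(n) - runif(n)) / n, numeric(n))
  u <- matrix(u, nrow = n)
  rng <- start_ranges(spec)
  lapply(seq_len(n), function(i) {
    setNames(rng$lo + (rng$hi - rng$lo) * u[i, ], spec$term)
  })
}

start_ranges <- function(spec) {
  ranges <- synthetic_parameter_ranges()
  lo <- spec$lower + 0.1 * (spec$upper - spec$lower)
  hi <- spec$upper - 0.1 * (spec$upper - spec$lower)
  for (i in seq_len(nrow(spec))) {
    term <- spec$term[i]
    key <- if (grepl("^theta_[va]_01$", term)) {
      sub("_01$", "_base", term)
    } else if (grepl("^theta_", term)) {
      sub("_[0-9]+$", "", term)
    } else {
      term
    }
    rng <- ranges[[key]]
    if (!is.null(rng)) {
      lo[i] <- max(rng[1], spec$lower[i])
      hi[i] <- min(rng[2], spec$upper[i])
    }
  }
  list(lo = lo, hi = hi)
}

# Flat-shape initializations for semiparametric fits: all three functions flat
# across the stimulus range, at a small grid of noise levels (the package's
# own grid of flat levels).
semiparametric_flat_starts <- function(spec) {
  levels_sigma <- c(1, 2, 4, 8)
  mid <- function(term) {
    i <- match(term, spec$term)
    (spec$lower[i] + spec$upper[i]) / 2
  }
  starts <- list()
  for (sv in levels_sigma) {
    for (sa in levels_sigma) {
      p <- setNames(rep(NA_real_, nrow(spec)), spec$term)
      p[sprintf("theta_v_%02d", 1:12)] <- c(log(sv), rep(LOG_INCREMENT_FLOOR, 11))
      p[sprintf("theta_a_%02d", 1:12)] <- c(log(sa), rep(LOG_INCREMENT_FLOOR, 11))
      p[sprintf("theta_p_%02d", 1:11)] <- LOG_INCREMENT_FLOOR # flat prior
      rest <- setdiff(spec$term, names(p)[!is.na(p)])
      p[rest] <- vapply(rest, mid, 0)
      p[["lambda"]] <- 0.02
      if ("rho_a" %in% spec$term) p[["rho_a"]] <- 1.1
      starts[[length(starts) + 1]] <- p
    }
  }
  starts
}

#' Fit a model by maximum likelihood with multi-start optimization
#'
#' Optimizes the transformed free-parameter vector from several
#' initializations (Latin-hypercube points within bounds, flat-shape starts
#' for semiparametric models, plus any supplied warm starts) and returns the
#' best solution across restarts.
#'
#' @param data Responded trial tibble (one participant).
#' @param model_name Registry model name.
#' @param tasks Optional task subset.
#' @param n_starts Number of restarts.
#' @param seed Integer seed controlling start points (restart substreams are
#'   derived with [derive_seed()]).
#' @param optimizer `"lbfgsb"`, `"neldermead"`, `"cmaes"`, a function obeying
#'   the optimizer contract, or `NULL` to choose by dimensionality (CMA-ES
#'   above 20 free parameters).
#' @param grids A [grid_spec()].
#' @param frozen Frozen shapes for lifted models.
#' @param warm_starts Optional list of named parameter vectors used as
#'   additional start points.
#' @param control List passed to the optimizer (e.g. `maxit`).
#' @return An `observer_fit` object.
#' @export
fit_mle <- function(data, model_name, tasks = NULL, n_starts = 4, seed = 1,
                    optimizer = NULL, grids = grid_spec(), frozen = NULL,
                    warm_starts = NULL, control = list()) {
  stopifnot(n_starts >= 1)
  if (!is.null(tasks)) data <- data[data$task %in% tasks, , drop = FALSE]
  task_scope <- if (!parse_model_name(model_name)$lifted &&
      all(data$task %in% c("UV", "UA"))) "unisensory" else "all"
  spec <- parameter_spec(model_name, task_scope)
  info <- attr(spec, "info")
  opt <- select_optimizer(optimizer, nrow(spec))

  objective <- function(t) {
    params <- from_unconstrained(spec, t)
    negative_log_likelihood(params, model_name, data, grids = grids,
      frozen = frozen)
  }

  set.seed(derive_seed(seed, "starts", model_name))
  starts <- latin_hypercube_starts(spec, n_starts)
  if (info$noise == "Semiparam" && !info$lifted) {
    flats <- semiparametric_flat_starts(spec)
    starts <- c(head(flats, n_starts), starts)[seq_len(max(n_starts, 1))]
  }
  starts <- c(warm_starts, starts)

  # two-phase multi-start: a cheap exploration run from every start, then a
  # deep polish of the most promising solution; the returned optimum is the
  # best point seen in any phase, so a warm start can never be degraded
  explore_control <- control
  explore_control$maxit <- control$explore_maxit %||%
    max(20, (control$maxit %||% 300) %/% 6)
  restarts <- vector("list", length(starts))
  best <- NULL
  for (i in seq_along(starts)) {
    set.seed(derive_seed(seed, "restart", model_name, i))
    t0 <- to_unconstrained(spec, check_params(spec, starts[[i]]))
    res <- opt$fun(objective, t0, if (length(starts) > 1) explore_control
      else control)
    restarts[[i]] <- tibble::tibble(
      restart = i, phase = "explore", start_nll = objective(t0),
      final_nll = res$value, n_eval = res$counts, convergence = res$convergence
    )
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (length(starts) > 1) {
    set.seed(derive_seed(seed, "polish", model_name))
    res <- opt$fun(objective, best$par, control)
    restarts[[length(restarts) + 1]] <- tibble::tibble(
      restart = length(starts) + 1L, phase = "polish", start_nll = best$value,
      final_nll = res$value, n_eval = res$counts, convergence = res$convergence
    )
    if (res$value < best$value) best <- res
  }
  params <- from_unconstrained(spec, best$par)
  structure(
    list(
      model_name = model_name, task_scope = task_scope,
      params = params, nll = best$value,
      restarts = dplyr::bind_rows(restarts),
      seed = seed, optimizer = opt$name,
      n_trials = nrow(data), data_digest = rlang::hash(data),
      spec = spec, frozen = frozen, grids = grids
    ),
    class = "observer_fit"
  )
}

#' @export
print.observer_fit <- function(x, ...) {
  cat("<observer_fit>", x$model_name, sprintf("(%s tasks)\n", x$task_scope))
  cat(sprintf("  NLL %.3f over %d trials; %d free parameters; %d restart(s); optimizer %s\n",
    x$nll, x$n_trials, length(x$params), nrow(x$restarts), x$optimizer))
  invisible(x)
}

#' Lift a unisensory semiparametric fit to all tasks
#'
#' Freezes the fitted shape parameters (12 visual + 12 auditory noise values
#' and 11 prior values) of a unisensory semiparametric fit and refits the nine
#' context parameters (`alpha_med`, `alpha_low`, `lambda`, `sigma_motor`,
#' `rho_a`, `p_same`, `beta_v`, `beta_a`, `gamma`) on all five tasks.
#'
#' @param unisensory_fit An `observer_fit` of the `Semiparametric` model.
#' @param data Responded all-task trial tibble for the same participant.
#' @param strategy Causal inference strategy of the lifted model.
#' @param ... Passed to [fit_mle()].
#' @return An `observer_fit` of the lifted model (with `frozen` recorded).
#' @export
lift_semiparametric <- function(unisensory_fit, data, strategy = "PM", ...) {
  if (!inherits(unisensory_fit, "observer_fit") ||
      parse_model_name(unisensory_fit$model_name)$noise != "Semiparam" ||
      unisensory_fit$task_scope != "unisensory") {
    abort("`unisensory_fit` must be a unisensory semiparametric fit.")
  }
  strategy <- match.arg(strategy, STRATEGIES)
  p <- unisensory_fit$params
  frozen <- list(
    theta_v = unname(p[sprintf("theta_v_%02d", 1:12)]),
    theta_a = unname(p[sprintf("theta_a_%02d", 1:12)]),
    theta_p = unname(p[sprintf("theta_p_%02d", 1:11)])
  )
  fit_mle(data, paste0("LiftedSemiparam-", strategy), frozen = frozen, ...)
}
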