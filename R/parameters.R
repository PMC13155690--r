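# Model naming, parameter inventories, bounds and transforms.
#
# Model names follow "noise-prior-strategy[_recal]": e.g. Exp-GaussianLaplace-PM,
# Const-SingleGaussian_1 (recalibration fixed at 1), Exp-GaussianLaplace_4/3
# (fixed at 4/3; absent suffix = free rho_a). The semiparametric model is
# "Semiparametric" (unisensory only); lifted fits are "LiftedSemiparam-MS/MA/PM".

NOISE_FAMILIES <- c("Const", "Exp", "Semiparam")
PRIOR_FAMILIES <- c("SingleGaussian", "TwoGaussians", "GaussianLaplace", "Semiparam")

#' Parse a model registry name
#'
#' @param model_name Model name string.
#' @return A list with `noise`, `prior`, `strategy` (or `NA`), `recal`
#'   (`"free"`, `"1"` or `"4/3"`), and `lifted` flag.
#' @export
#' @examples
#' parse_model_name("Exp-GaussianLaplace-PM")
#' parse_model_name("Const-SingleGaussian_1")
parse_model_name <- function(model_name) {
  recal <- "free"
  base <- model_name
  if (grepl("_4/3$", base)) {
    recal <- "4/3"
    base <- sub("_4/3$", "", base)
  } else if (grepl("_1$", base)) {
    recal <- "1"
    base <- sub("_1$", "", base)
  }
  parts <- strsplit(base, "-", fixed = TRUE)[[1]]
  if (parts[1] == "LiftedSemiparam") {
    if (length(parts) != 2 || !parts[2] %in% STRATEGIES) {
      abort("Lifted models are named LiftedSemiparam-MS/MA/PM.")
    }
    return(list(noise = "Semiparam", prior = "Semiparam", strategy = parts[2],
      recal = recal, lifted = TRUE))
  }
  if (parts[1] == "Semiparametric") {
    return(list(noise = "Semiparam", prior = "Semiparam", strategy = NA_character_,
      recal = recal, lifted = FALSE))
  }
  if (length(parts) < 2 || !parts[1] %in% NOISE_FAMILIES ||
      !parts[2] %in% PRIOR_FAMILIES) {
    abort(sprintf("Malformed model name '%s'.", model_name))
  }
  strategy <- if (length(parts) >= 3) parts[3] else NA_character_
  if (!is.na(strategy) && !strategy %in% STRATEGIES) {
    abort(sprintf("Unknown causal inference strategy '%s'.", strategy))
  }
  list(noise = parts[1], prior = parts[2], strategy = strategy, recal = recal,
    lifted = FALSE)
}

param_row <- function(term, lower, upper, role) {
  tibble::tibble(term = term, lower = lower, upper = upper, role = role)
}

noise_param_rows <- function(family, modality) {
  suffix <- tolower(modality)
  role <- paste0("noise_", suffix)
  switch(family,
    Const = param_row(paste0("sigma0_", suffix), 0.05, 30, role),
    Exp = dplyr::bind_rows(
      param_row(paste0("sigma0_", suffix), 0.05, 30, role),
      param_row(paste0("k1_", suffix), 0, 40, role),
      param_row(paste0("k2_", suffix), 1e-3, 5, role)
    ),
    Semiparam = param_row(sprintf("theta_%s_%02d", suffix, 1:12),
      LOG_INCREMENT_FLOOR, log(40), role)
  )
}

prior_param_rows <- function(family) {
  switch(family,
    SingleGaussian = param_row("sigma_s", 0.25, 60, "prior"),
    TwoGaussians = dplyr::bind_rows(
      param_row("sigma_s", 0.25, 60, "prior"),
      param_row("sigma_delta", 0.25, 60, "prior"),
      param_row("omega", 1e-4, 1 - 1e-4, "prior")
    ),
    GaussianLaplace = dplyr::bind_rows(
      param_row("sigma_s", 0.25, 60, "prior"),
      param_row("b", 0.25, 60, "prior"),
      param_row("omega", 1e-4, 1 - 1e-4, "prior")
    ),
    Semiparam = param_row(sprintf("theta_p_%02d", 1:11),
      LOG_INCREMENT_FLOOR, log(20), "prior")
  )
}

context_param_rows <- function(task_scope, recal, lifted) {
  rows <- dplyr::bind_rows(
    param_row("alpha_med", 0.2, 10, "context"),
    param_row("alpha_low", 0.2, 10, "context"),
    param_row("lambda", 1e-4, 1 - 1e-4, "context"),
    param_row("sigma_motor", 0.05, 30, "context")
  )
  if (recal == "free") {
    rows <- dplyr::bind_rows(rows, param_row("rho_a", 0.5, 2, "context"))
  }
  if (task_scope == "all") {
    rows <- dplyr::bind_rows(rows,
      param_row("p_same", 1e-4, 1 - 1e-4, "context"),
      param_row("beta_v", 0.2, 10, "context"),
      param_row("beta_a", 0.2, 10, "context"))
  }
  if (lifted) {
    rows <- dplyr::bind_rows(rows, param_row("gamma", 0, 5, "context"))
  }
  rows
}

#' Free-parameter specification of a model
#'
#' Ordered free parameters of a registry model with bounds, transform and role
#' tags. Frozen parameters (the 35 shape values of a lifted fit) and fixed
#' recalibration constants are excluded from the optimizer vector; the fixed
#' recalibration value, if any, is recorded in the `fixed` attribute, and the
#' frozen shape-parameter count in the `n_frozen` attribute.
#'
#' @param model_name Registry model name.
#' @param task_scope `"unisensory"` (UV + UA) or `"all"` (five tasks).
#' @return A tibble with columns `term`, `lower`, `upper`, `transform`, `role`.
#' @export
#' @examples
#' nrow(parameter_spec("Exp-GaussianLaplace-PM", "all")) # 17
#' nrow(parameter_spec("Semiparametric", "unisensory")) # 40
parameter_spec <- function(model_name, task_scope = c("unisensory", "all")) {
  task_scope <- match.arg(task_scope)
  key <- paste(model_name, task_scope)
  cached <- .spec_cache[[key]]
  if (!is.null(cached)) return(cached)
  info <- parse_model_name(model_name)
  if (info$lifted && task_scope != "all") {
    abort("Lifted models are fitted on all tasks.")
  }
  if (is.na(info$strategy) && task_scope == "all" && !info$lifted) {
    abort("All-task fits need a causal inference strategy in the model name.")
  }
  shape_rows <- if (info$lifted) {
    NULL # shapes frozen from the upstream semiparametric fit
  } else {
    dplyr::bind_rows(
      noise_param_rows(info$noise, "V"),
      noise_param_rows(info$noise, "A"),
      prior_param_rows(info$prior)
    )
  }
  rows <- dplyr::bind_rows(shape_rows,
    context_param_rows(task_scope, info$recal, info$lifted))
  rows$transform <- "logit" # scaled logit onto [lower, upper]
  spec <- rows[, c("term", "lower", "upper", "transform", "role")]
  attr(spec, "model_name") <- model_name
  attr(spec, "task_scope") <- task_scope
  attr(spec, "info") <- info
  attr(spec, "fixed") <- switch(info$recal, free = list(),
    `1` = list(rho_a = 1), `4/3` = list(rho_a = 4 / 3))
  attr(spec, "n_frozen") <- if (info$lifted) 35L else 0L
  .spec_cache[[key]] <- spec
  spec
}

# memoization cache for parameter specifications (built once per model name)
.spec_cache <- new.env(parent = emptyenv())

#' Models of the registry
#'
#' @param task_scope `"unisensory"` or `"all"`.
#' @return Character vector of model names buildable for the scope.
#' @export
list_models <- function(task_scope = c("all", "unisensory")) {
  task_scope <- match.arg(task_scope)
  combos <- c("Exp-GaussianLaplace", "Exp-SingleGaussian", "Const-GaussianLaplace",
    "Exp-TwoGaussians", "Const-SingleGaussian")
  if (task_scope == "unisensory") {
    c(paste0("Const-SingleGaussian", c("_1", "_4/3", "")),
      paste0("Exp-GaussianLaplace", c("_1", "_4/3", "")),
      "Exp-SingleGaussian", "Const-GaussianLaplace", "Exp-TwoGaussians",
      "Semiparametric")
  } else {
    c(t(outer(combos, STRATEGIES, paste, sep = "-")),
      paste0("LiftedSemiparam-", STRATEGIES))
  }
}

# --- parameter transforms ----------------------------------------------------

# Scaled logit: bijection from [lower, upper] onto the real line.
to_unconstrained <- function(spec, params) {
  params <- params[spec$term]
  u <- (params - spec$lower) / (spec$upper - spec$lower)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  setNames(qlogis(u), spec$term)
}

from_unconstrained <- function(spec, t) {
  setNames(spec$lower + (spec$upper - spec$lower) * plogis(t), spec$term)
}

check_params <- function(spec, params) {
  if (is.null(names(params)) || !setequal(names(params), spec$term)) {
    missing <- setdiff(spec$term, names(params))
    extra <- setdiff(names(params), spec$term)
    abort(paste0("Parameter vector does not match the model's free parameters.",
      if (length(missing)) paste0(" Missing: ", paste(missing, collapse = ", "), "."),
      if (length(extra)) paste0(" Unexpected: ", paste(extra, collapse = ", "), ".")))
  }
  params <- params[spec$term]
  if (any(!is.finite(params))) abort("Parameters must be finite.")
  if (any(params < spec$lower - 1e-9 | params > spec$upper + 1e-9)) {
    bad <- spec$term[params < spec$lower - 1e-9 | params > spec$upper + 1e-9]
    abort(paste0("Parameter(s) outside bounds: ", paste(bad, collapse = ", ")))
  }
  params
}

# --- observer assembly -------------------------------------------------------

build_prior_component <- function(info, params, frozen) {
  if (info$prior == "Semiparam") {
    theta <- if (info$lifted) frozen$theta_p else
      unname(params[sprintf("theta_p_%02d", 1:11)])
    prior_semiparametric(theta)
  } else if (info$prior == "SingleGaussian") {
    prior_single_gaussian(params[["sigma_s"]])
  } else if (info$prior == "TwoGaussians") {
    prior_two_gaussians(params[["sigma_s"]], params[["sigma_delta"]],
      params[["omega"]])
  } else {
    prior_gaussian_laplace(params[["sigma_s"]], params[["b"]], params[["omega"]])
  }
}

build_noise_component <- function(info, params, frozen, modality) {
  sfx <- tolower(modality)
  if (info$noise == "Semiparam") {
    theta <- if (info$lifted) frozen[[paste0("theta_", sfx)]] else
      unname(params[sprintf("theta_%s_%02d", sfx, 1:12)])
    noise_semiparametric(theta, modality = modality)
  } else if (info$noise == "Const") {
    noise_const(params[[paste0("sigma0_", sfx)]], modality)
  } else {
    noise_exp(params[[paste0("sigma0_", sfx)]], params[[paste0("k1_", sfx)]],
      params[[paste0("k2_", sfx)]], modality)
  }
}

#' Assemble an observer model from a registry name and parameter vector
#'
#' @param model_name Registry model name.
#' @param params Named vector of the model's free parameters.
#' @param task_scope `"unisensory"` or `"all"`.
#' @param grids A [grid_spec()].
#' @param frozen For lifted models, the frozen shape parameters as a list with
#'   `theta_v`, `theta_a` (12 values each) and `theta_p` (11 values).
#' @return An [observer_model()].
#' @export
assemble_observer <- function(model_name, params, task_scope = "unisensory",
                              grids = grid_spec(), frozen = NULL) {
  spec <- parameter_spec(model_name, task_scope)
  info <- attr(spec, "info")
  params <- check_params(spec, params)
  if (info$lifted && (is.null(frozen) ||
      !all(c("theta_v", "theta_a", "theta_p") %in% names(frozen)))) {
    abort("Lifted models need frozen shape parameters (theta_v, theta_a, theta_p).")
  }
  fixed <- attr(spec, "fixed")
  get <- function(name, default) {
    if (name %in% names(params)) params[[name]]
    else if (name %in% names(fixed)) fixed[[name]]
    else default
  }
  ctx <- context_params(
    alpha_med = params[["alpha_med"]], alpha_low = params[["alpha_low"]],
    beta_v = get("beta_v", 1), beta_a = get("beta_a", 1),
    rho_a = get("rho_a", 1), p_same = get("p_same", 0.5),
    lambda = params[["lambda"]], sigma_motor = params[["sigma_motor"]],
    gamma = get("gamma", 1)
  )
  observer_model(
    prior = build_prior_component(info, params, frozen),
    noise_v = build_noise_component(info, params, frozen, "V"),
    noise_a = build_noise_component(info, params, frozen, "A"),
    strategy = if (is.na(info$strategy)) "PM" else info$strategy,
    context = ctx, grids = grids
  )
}

# --- synthetic parameter ranges ----------------------------------------------

#' Synthetic-data parameter ranges
#'
#' Sampling ranges used when drawing synthetic participants (see
#' [make_simulated_group()]). Shipped as a plain-text fixture in
#' `inst/extdata/synthetic_params.json`; these are the package's own choices of
#' realistic values (documented in the methods vignette), not any participant's
#' fitted parameters.
#'
#' @return Named list of `[lower, upper]` ranges.
#' @export
synthetic_parameter_ranges <- function() {
  if (is.null(.spec_cache$synthetic_ranges)) {
    path <- system.file("extdata", "synthetic_params.json", package = "causalobs")
    .spec_cache$synthetic_ranges <- jsonlite::fromJSON(path)
  }
  .spec_cache$synthetic_ranges
}

#' Draw a synthetic participant's parameter vector
#'
#' Samples each free parameter of a model uniformly within the package's
#' synthetic ranges (intersected with the fitting bounds); parameters without
#' a listed range fall back to their full bound interval.
#'
#' @param spec A [parameter_spec()].
#' @param seed Integer seed.
#' @return A named parameter vector.
#' @export
#' @examples
#' draw_synthetic_params(parameter_spec("Const-SingleGaussian", "unisensory"), 1)
draw_synthetic_params <- function(spec, seed) {
  ranges <- synthetic_parameter_ranges()
  set.seed(seed)
  vals <- vapply(seq_len(nrow(spec)), function(i) {
    term <- spec$term[i]
    key <- if (grepl("^theta_[va]_01$", term)) {
      sub("_01$", "_base", term)
    } else if (grepl("^theta_", term)) {
      sub("_[0-9]+$", "", term)
    } else {
      term
    }
    rng <- ranges[[key]]
    if (is.null(rng)) rng <- c(spec$lower[i], spec$upper[i])
    lo <- max(rng[1], spec$lower[i])
    hi <- min(rng[2], spec$upper[i])
    runif(1, lo, hi)
  }, 0)
  setNames(vals, spec$term)
}
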