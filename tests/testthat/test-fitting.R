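make_uni_data <- function(n_uv = 150, n_ua = 150, observer = NULL, seed = 21) {
  obs <- observer %||% vanilla_observer(grids = recovery_grids())
  tr <- sample_experiment(experiment_design(n_participants = 1,
    trials_per_task = c(UV = n_uv, UA = n_ua, B = 1, BC = 1)), seed = seed)
  simulate_responses(tr[tr$task %in% c("UV", "UA"), ], obs, seed = seed + 1)
}

test_that("the NLL objective follows the summed-log contract", {
  g <- recovery_grids()
  dat <- make_uni_data()
  spec <- parameter_spec("Const-SingleGaussian", "unisensory")
  params <- c(sigma0_v = 2, sigma0_a = 3, sigma_s = 10, alpha_med = 2,
    alpha_low = 3.5, lambda = 0.03, sigma_motor = 0.8, rho_a = 4 / 3)

  # pure lapse: every localization trial has density 1/90
  lapse <- params
  lapse[["lambda"]] <- 1 - 1e-4
  nll <- negative_log_likelihood(lapse, "Const-SingleGaussian", dat, grids = g)
  expect_equal(nll, nrow(dat) * log(90), tolerance = 1e-3)

  # additivity over disjoint trial subsets
  n_all <- negative_log_likelihood(params, "Const-SingleGaussian", dat, grids = g)
  n_uv <- negative_log_likelihood(params, "Const-SingleGaussian", dat,
    tasks = "UV", grids = g)
  n_ua <- negative_log_likelihood(params, "Const-SingleGaussian", dat,
    tasks = "UA", grids = g)
  expect_equal(n_all, n_uv + n_ua, tolerance = 1e-9)

  # invariance to trial order
  set.seed(1)
  shuffled <- dat[sample(nrow(dat)), ]
  expect_equal(negative_log_likelihood(params, "Const-SingleGaussian", shuffled,
    grids = g), n_all, tolerance = 1e-9)
})

test_that("cached group evaluation matches trial-by-trial re-evaluation", {
  # per-trial probabilities recomputed with all caching bypassed (fields and
  # tables rebuilt per trial on identical absolute grids)
  g <- grid_spec(s_points = 181, x_points = 41, x_points_2d = 21,
    shat_spacing = 0.5, field_spacing = 0.5)
  obs <- rich_observer(grids = g)
  tr <- sample_experiment(small_design(1, 12, 12, 16, 16), seed = 31)
  tr <- simulate_responses(tr, obs, seed = 32)
  cached <- causalobs:::trial_likelihood(obs, tr, use_cache = TRUE)
  direct <- causalobs:::trial_likelihood(obs, tr, use_cache = FALSE)
  expect_equal(cached, direct, tolerance = 1e-8)
})

test_that("parameter transforms roundtrip to machine precision", {
  for (model in c("Exp-GaussianLaplace-PM", "Semiparametric",
    "Const-SingleGaussian_1")) {
    scope <- if (model == "Exp-GaussianLaplace-PM") "all" else "unisensory"
    spec <- parameter_spec(model, scope)
    set.seed(5)
    params <- causalobs:::draw_synthetic_params(spec, 5)
    t <- causalobs:::to_unconstrained(spec, params)
    back <- causalobs:::from_unconstrained(spec, t)
    expect_equal(back, params[spec$term], tolerance = 1e-10)
  }
})

test_that("maximum-likelihood fitting recovers a vanilla observer", {
  g <- recovery_grids()
  truth <- c(sigma0_v = 2, sigma0_a = 3.5, sigma_s = 6, alpha_med = 2,
    alpha_low = 4, lambda = 0.1, sigma_motor = 1.2, rho_a = 4 / 3)
  obs <- assemble_observer("Const-SingleGaussian", truth, "unisensory", g)
  dat <- make_uni_data(1500, 1500, observer = obs, seed = 41)
  fit <- fit_mle(dat, "Const-SingleGaussian", n_starts = 2, seed = 6, grids = g,
    control = list(maxit = 250, explore_maxit = 40))
  nll_truth <- negative_log_likelihood(truth, "Const-SingleGaussian", dat,
    grids = g)
  expect_lte(fit$nll, nll_truth + 1e-6)
  for (term in c("sigma0_v", "sigma0_a", "sigma_s", "lambda", "sigma_motor")) {
    expect_lt(abs(fit$params[[term]] - truth[[term]]) / truth[[term]], 0.15)
  }
  # tidiers
  td <- tidy(fit)
  expect_equal(td$term, fit$spec$term)
  gl <- glance(fit)
  expect_equal(gl$aic, 2 * fit$nll + 2 * 8)
})

test_that("warm starts are never degraded and nesting holds", {
  g <- recovery_grids()
  truth <- c(sigma0_v = 2, sigma0_a = 3.5, sigma_s = 9, alpha_med = 2,
    alpha_low = 3.5, lambda = 0.04, sigma_motor = 0.8, rho_a = 4 / 3)
  obs <- assemble_observer("Const-SingleGaussian", truth, "unisensory", g)
  dat <- make_uni_data(120, 120, observer = obs, seed = 51)
  nll_truth <- negative_log_likelihood(truth, "Const-SingleGaussian", dat,
    grids = g)
  fit <- fit_mle(dat, "Const-SingleGaussian", n_starts = 1, seed = 2, grids = g,
    warm_starts = list(truth), control = list(maxit = 150, explore_maxit = 30))
  expect_lte(fit$nll, nll_truth + 1e-6)

  # a nesting model (Exp noise contains Const at k1 = 0) cannot fit worse when
  # warm-started from the smaller model's solution
  up <- c(fit$params[c("sigma0_v")], k1_v = 0.01, k2_v = 0.5,
    sigma0_a = unname(fit$params[["sigma0_a"]]), k1_a = 0.01, k2_a = 0.5,
    fit$params[c("sigma_s", "alpha_med", "alpha_low", "lambda", "sigma_motor",
      "rho_a")])
  names(up)[1] <- "sigma0_v"
  fit2 <- fit_mle(dat, "Exp-SingleGaussian", n_starts = 1, seed = 3, grids = g,
    warm_starts = list(up), control = list(maxit = 120, explore_maxit = 30))
  expect_lte(fit2$nll, fit$nll + 0.51) # k1 floor offset + optimizer tolerance
})

test_that("fits are reproducible for a fixed seed and data", {
  g <- recovery_grids()
  dat <- make_uni_data(80, 80)
  f1 <- fit_mle(dat, "Const-SingleGaussian_1", n_starts = 2, seed = 9,
    grids = g, control = list(maxit = 40, explore_maxit = 15))
  f2 <- fit_mle(dat, "Const-SingleGaussian_1", n_starts = 2, seed = 9,
    grids = g, control = list(maxit = 40, explore_maxit = 15))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$nll, f2$nll)
  expect_equal(f1$nll, min(f1$restarts$final_nll))
  expect_identical(f1$data_digest, f2$data_digest)
})

test_that("the CMA-ES optimizer minimizes a smooth multimodal-free objective", {
  # our own evolution strategy implementation, checked on a shifted quadratic
  set.seed(1)
  target <- c(1.5, -2, 0.5, 3, -1)
  fn <- function(x) sum((x - target)^2) + 1
  res <- causalobs:::optimizer_cmaes(fn, rep(0, 5),
    control = list(maxeval = 6000, sigma0 = 1))
  expect_lt(res$value, 1 + 1e-4)
  expect_equal(res$par, target, tolerance = 1e-2)
})

test_that("lifted fits freeze shapes and expose exactly nine free parameters", {
  g <- grid_spec(s_points = 181, x_points = 41, x_points_2d = 21,
    shat_spacing = 0.5, field_spacing = 0.5)
  spec <- parameter_spec("Semiparametric", "unisensory")
  set.seed(2)
  uni_params <- causalobs:::draw_synthetic_params(spec, 13)
  obs <- assemble_observer("Semiparametric", uni_params, "unisensory", g)
  tr <- sample_experiment(small_design(1, 60, 60, 60, 60), seed = 61)
  dat <- simulate_responses(tr, obs, seed = 62)

  uni_fit <- structure(list(model_name = "Semiparametric",
    task_scope = "unisensory", params = uni_params,
    nll = NA_real_, spec = spec), class = "observer_fit")
  lifted <- lift_semiparametric(uni_fit, dat, strategy = "PM", n_starts = 1,
    seed = 8, grids = g, control = list(maxit = 60))
  expect_length(lifted$params, 9)
  expect_setequal(names(lifted$params), c("alpha_med", "alpha_low", "lambda",
    "sigma_motor", "rho_a", "p_same", "beta_v", "beta_a", "gamma"))
  expect_equal(lifted$frozen$theta_v, unname(uni_params[sprintf("theta_v_%02d", 1:12)]))

  # gamma = 1 with the unisensory context parameters reproduces the
  # unisensory NLL on the unisensory subset: identical model, identical data
  ctx <- uni_params[c("alpha_med", "alpha_low", "lambda", "sigma_motor", "rho_a")]
  lifted_params <- c(ctx, p_same = 0.5, beta_v = 1, beta_a = 1, gamma = 1)
  nll_lift <- negative_log_likelihood(lifted_params, "LiftedSemiparam-PM",
    dat, tasks = c("UV", "UA"), grids = g, frozen = lifted$frozen)
  nll_uni <- negative_log_likelihood(uni_params, "Semiparametric",
    dat, tasks = c("UV", "UA"), grids = g)
  expect_equal(nll_lift, nll_uni, tolerance = 1e-8)
})
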