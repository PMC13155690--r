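# Shared fixtures: small observer models and trial tables built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

vanilla_observer <- function(sigma_s = 10, sigma0_v = 2, sigma0_a = 3,
                             sigma_motor = 0.8, lambda = 0.03, rho_a = 4 / 3,
                             p_same = 0.6, beta_v = 1.2, beta_a = 1.5,
                             alpha_med = 2, alpha_low = 3.5, strategy = "PM",
                             grids = grid_spec()) {
  observer_model(
    prior = prior_single_gaussian(sigma_s),
    noise_v = noise_const(sigma0_v, "V"),
    noise_a = noise_const(sigma0_a, "A"),
    strategy = strategy,
    context = context_params(alpha_med = alpha_med, alpha_low = alpha_low,
      beta_v = beta_v, beta_a = beta_a, rho_a = rho_a, p_same = p_same,
      lambda = lambda, sigma_motor = sigma_motor),
    grids = grids
  )
}

rich_observer <- function(strategy = "PM", grids = grid_spec()) {
  observer_model(
    prior = prior_gaussian_laplace(sigma_s = 9, b = 2.5, omega = 0.55),
    noise_v = noise_exp(1.1, 3.5, 0.3, "V"),
    noise_a = noise_exp(3, 4, 0.2, "A"),
    strategy = strategy,
    context = context_params(alpha_med = 1.8, alpha_low = 3.6, beta_v = 1.15,
      beta_a = 1.55, rho_a = 4 / 3, p_same = 0.55, lambda = 0.04,
      sigma_motor = 0.9),
    grids = grids
  )
}

small_design <- function(n_participants = 1, uv = 40, ua = 40, b = 40, bc = 40) {
  experiment_design(n_participants = n_participants,
    trials_per_task = c(UV = uv, UA = ua, B = b, BC = bc))
}

# conjugate-Gaussian shrinkage weight
shrink_w <- function(sigma_s, sigma) sigma_s^2 / (sigma_s^2 + sigma^2)
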