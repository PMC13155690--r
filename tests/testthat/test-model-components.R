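s_grid <- seq(-45, 45, length.out = 721)

test_that("parametric priors evaluate their closed forms and normalize", {
  # Gaussian-Laplace mixture density at the center
  pr <- prior_gaussian_laplace(sigma_s = 8, b = 2, omega = 0.4)
  expected0 <- 0.6 / (8 * sqrt(2 * pi)) + 0.4 / (2 * 2)
  z <- pr$norm_const
  expect_equal(prior_pdf(pr, 0), expected0 / z, tolerance = 1e-12)

  # degenerate two-Gaussian mixture collapses to the single Gaussian
  pr2 <- prior_two_gaussians(sigma_s = 6, sigma_delta = 5, omega = 1e-12)
  pr1 <- prior_single_gaussian(6)
  expect_equal(prior_pdf(pr2, s_grid), prior_pdf(pr1, s_grid), tolerance = 1e-9)

  # unit mass, symmetry, non-negativity for every family
  priors <- list(
    prior_single_gaussian(7),
    prior_two_gaussians(5, 12, 0.3),
    prior_gaussian_laplace(9, 2.5, 0.55),
    prior_semiparametric(seq(-3, -0.5, length.out = 11))
  )
  for (pr in priors) {
    dens <- prior_pdf(pr, s_grid)
    expect_true(all(dens >= 0))
    expect_equal(trapz(s_grid, dens), 1, tolerance = 1e-6)
    expect_equal(dens, rev(dens), tolerance = 1e-12)
  }
})

test_that("semiparametric prior builder follows the log-decrement construction", {
  pivots <- pivot_grid()
  theta <- log(seq(0.1, 0.6, length.out = 11))
  pr <- prior_semiparametric(theta)
  log_expected <- c(0, -cumsum(exp(theta)))
  at_pivots <- prior_pdf(pr, pivots)
  # pivot values reproduced exactly (up to the shared normalization constant)
  expect_equal(log(at_pivots) - log(at_pivots[1]), log_expected,
    tolerance = 1e-10)
  # non-increasing in |s| everywhere at 0.1-degree resolution
  fine <- seq(0, 45, by = 0.1)
  expect_true(all(diff(prior_pdf(pr, fine)) <= 1e-12))

  # flat limit: uniform density 1/90 per degree
  flat <- prior_semiparametric(rep(log(1e-6), 11))
  expect_equal(prior_pdf(flat, c(-30, 0, 12)), rep(1 / 90, 3), tolerance = 1e-4)

  expect_error(prior_semiparametric(rep(0, 10)), "11")
})

test_that("semiparametric noise builder follows the cumulative-sum construction", {
  nm <- noise_semiparametric(rep(log(1), 12))
  expect_equal(noise_sigma(nm, pivot_grid()), 1:12, tolerance = 1e-12)

  # flat shape at 2 degrees
  flat <- noise_semiparametric(c(log(2), rep(log(1e-6), 11)))
  expect_equal(noise_sigma(flat, c(0, 10, 45)), rep(2, 3), tolerance = 1e-4)

  # interpolation passes through the pivots exactly; monotone between them
  theta <- c(log(1.5), log(seq(0.2, 1, length.out = 11)))
  nm2 <- noise_semiparametric(theta)
  expect_equal(noise_sigma(nm2, pivot_grid()), cumsum(exp(theta)),
    tolerance = 1e-12)
  fine <- seq(0, 45, by = 0.1)
  expect_true(all(diff(noise_sigma(nm2, fine)) >= -1e-12))

  expect_error(noise_semiparametric(rep(0, 11)), "12")
})

test_that("noise families are symmetric, positive and correctly scaled", {
  ctx <- context_params(alpha_med = 2, alpha_low = 3.5, beta_v = 1.2,
    beta_a = 1.6)
  s <- seq(-45, 45, by = 0.5)
  for (nm in list(noise_const(2), noise_exp(1, 4, 0.3),
    noise_semiparametric(c(0, seq(-3, -1, length.out = 11))))) {
    sig <- noise_sigma(nm, s)
    expect_true(all(sig > 0))
    expect_equal(sig, rev(sig), tolerance = 1e-12)
  }

  # exponential: sigma0 at the center, sigma0 + k1 in the far periphery
  nm <- noise_exp(1.5, 4, 0.3)
  expect_equal(noise_sigma(nm, 0), 1.5)
  expect_equal(noise_sigma(nm, 1e3 / 0.3), 5.5, tolerance = 1e-8)
  # Exp with k1 = 0 equals Const everywhere
  expect_equal(noise_sigma(noise_exp(2, 0, 1), s), noise_sigma(noise_const(2), s))

  # reliability and bisensory multipliers compose on the base shape
  cv <- noise_const(2, "V")
  expect_equal(noise_sigma(cv, 5, "low", ctx, bisensory = TRUE), 2 * 3.5 * 1.2)
  expect_equal(noise_sigma(cv, 5, "medium", ctx), 2 * 2)
  ca <- noise_const(3, "A")
  expect_equal(noise_sigma(ca, 5, NULL, ctx, bisensory = TRUE), 3 * 1.6)
  # reliability scaling applies to vision only
  expect_error(noise_sigma(ca, 5, "low", ctx), "visual")
})

test_that("auditory recalibration is a pure multiplicative gain", {
  expect_equal(apply_recalibration(c(-3, 0, 9), 1), c(-3, 0, 9))
  expect_equal(apply_recalibration(9, 4 / 3), 12)
  expect_equal(apply_recalibration(0, 1.7), 0)
})

test_that("prior exponent reshapes and renormalizes the density", {
  pr <- prior_gaussian_laplace(8, 2, 0.5)
  expect_equal(prior_pdf(apply_prior_exponent(pr, 1), s_grid),
    prior_pdf(pr, s_grid))
  # gamma = 0: uniform over the support
  expect_equal(prior_pdf(apply_prior_exponent(pr, 0), c(-20, 0, 33)),
    rep(1 / 90, 3), tolerance = 1e-12)
  # gamma = 2 on a Gaussian: Gaussian with SD / sqrt(2) (support >> SD)
  sq <- apply_prior_exponent(prior_single_gaussian(5), 2)
  expect_equal(prior_pdf(sq, s_grid), prior_pdf(prior_single_gaussian(5 / sqrt(2)),
    s_grid), tolerance = 1e-6)
  # exponentiated priors still integrate to one
  expect_equal(trapz(s_grid, prior_pdf(apply_prior_exponent(pr, 1.7), s_grid)),
    1, tolerance = 1e-6)
})

test_that("pivot grid matches the semiparametric shape specification", {
  pv <- pivot_grid()
  expect_length(pv, 12)
  expect_equal(pv[1], 0)
  expect_equal(pv[12], 45)
  expect_true(all(diff(pv) > 0))
})
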