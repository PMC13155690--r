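# The conjugate-Gaussian closed forms in helper-oracles.R are the independent
# reference for the quadrature engine throughout this file.

test_that("unisensory posterior means match conjugate shrinkage", {
  obs <- vanilla_observer()
  # symmetry: zero measurement maps to zero estimate
  expect_equal(posterior_mean_unisensory(0, obs, "V"), 0, tolerance = 1e-10)
  # equal prior and noise SDs shrink by one half
  obs_eq <- vanilla_observer(sigma_s = 10, sigma0_v = 10)
  expect_equal(posterior_mean_unisensory(10, obs_eq, "V"), 5, tolerance = 1e-4)
  # general shrinkage weight over the stimulus range
  x <- seq(-20, 20, by = 2.5)
  w <- shrink_w(10, 2)
  expect_equal(posterior_mean_unisensory(x, obs, "V"), w * x, tolerance = 1e-3)
})

test_that("unisensory response densities match the conjugate closed form", {
  obs <- vanilla_observer()
  r_grid <- seq(-30, 30, by = 1.5)
  for (s in c(-12, 0, 7, 15)) {
    eng <- response_distribution_unisensory(s, obs, "UV", "high", r = r_grid)
    expect_equal(eng$density,
      oracle_unisensory_density(obs, "V", s, r_grid), tolerance = 1e-4)
    eng_a <- response_distribution_unisensory(s, obs, "UA", r = r_grid)
    expect_equal(eng_a$density,
      oracle_unisensory_density(obs, "A", s, r_grid), tolerance = 1e-4)
  }
  # mean of the response distribution equals the shrunk stimulus (lambda = 0)
  obs0 <- vanilla_observer(lambda = 0)
  full <- response_distribution_unisensory(10, obs0, "UV", "medium")
  m <- trapz(full$r, full$r * full$density)
  expect_equal(m, shrink_w(10, 2 * 2) * 10, tolerance = 1e-3)
})

test_that("pure-lapse observers respond uniformly", {
  obs <- vanilla_observer(lambda = 1)
  d <- response_distribution_unisensory(5, obs, "UV", "low",
    r = c(-44, -10, 0, 17, 44))
  expect_equal(d$density, rep(1 / 90, 5), tolerance = 1e-12)
  p <- bc_response_probability(c(0, 10), c(5, -5), "high", obs)
  expect_equal(p, c(0.5, 0.5), tolerance = 1e-12)
  db <- bisensory_localization_density(3, -3, "high", obs, "V",
    r = c(-20, 0, 20))
  expect_equal(db, rep(1 / 90, 3), tolerance = 1e-12)
})

test_that("causal posterior matches the conjugate closed form", {
  obs <- vanilla_observer()
  xv <- c(-10, 0, 5, 8, 14)
  xa <- c(-12, 2, 5, -3, 16)
  expect_equal(causal_posterior(xv, xa, obs, "medium"),
    oracle_pc1(obs, xv, xa, "medium"), tolerance = 1e-4)
  # degenerate priors over the causal structure
  obs1 <- vanilla_observer(p_same = 1)
  expect_equal(causal_posterior(xv, xa, obs1, "high"), rep(1, 5))
  obs0 <- vanilla_observer(p_same = 0)
  expect_equal(causal_posterior(xv, xa, obs0, "high"), rep(0, 5))
})

test_that("bisensory posterior means match the conjugate closed forms", {
  obs <- vanilla_observer()
  xv <- c(-10, 0, 6, 9)
  xa <- c(-4, 0, 2, 12)
  pm <- posterior_means_bisensory(xv, xa, obs, "V", "medium")
  expect_equal(pm$shat_c1, oracle_fused_mean(obs, xv, xa, "medium"),
    tolerance = 1e-3)
  expect_equal(pm$shat_c2, oracle_single_mean(obs, xv, "V", "medium"),
    tolerance = 1e-3)
  # symmetric inputs give zero estimates
  pm0 <- posterior_means_bisensory(0, 0, obs, "A")
  expect_equal(unlist(pm0), c(shat_c1 = 0, shat_c2 = 0), tolerance = 1e-10)
  # the C = 2 estimate for target V ignores the auditory measurement
  pm1 <- posterior_means_bisensory(rep(4, 3), c(-9, 0, 9), obs, "V")
  expect_equal(diff(range(pm1$shat_c2)), 0, tolerance = 1e-12)
})

test_that("BC response probabilities match the oracle for every strategy", {
  sv <- c(0, 5, -10, 12)
  sa <- c(0, -5, 10, 10)
  for (st in c("MS", "MA", "PM")) {
    obs <- vanilla_observer(strategy = st)
    eng <- bc_response_probability(sv, sa, "medium", obs)
    ora <- vapply(seq_along(sv), function(i) {
      oracle_bc_probability(obs, sv[i], sa[i], "medium")
    }, 0)
    expect_lt(max(abs(eng - ora)), 1e-3)
    # MS and MA are equivalent for the causal judgment
    if (st == "MA") {
      expect_equal(eng, bc_response_probability(sv, sa, "medium",
        vanilla_observer(strategy = "MS")), tolerance = 1e-9)
    }
  }
  # p_same = 1 with no lapse: certain "same" under any strategy
  for (st in c("MS", "PM")) {
    obs1 <- vanilla_observer(p_same = 1, lambda = 0, strategy = st)
    expect_equal(bc_response_probability(0, 5, "high", obs1), 1,
      tolerance = 1e-9)
  }
})

test_that("bisensory localization densities match the oracle for every strategy", {
  sv <- c(0, 5, -10)
  sa <- c(0, -5, 10)
  r <- c(1, -2, 3)
  for (st in c("MS", "MA", "PM")) {
    obs <- vanilla_observer(strategy = st)
    for (tg in c("V", "A")) {
      eng <- bisensory_localization_density(sv, sa, "medium", obs, tg, r)
      ora <- vapply(seq_along(sv), function(i) {
        oracle_bva_density(obs, sv[i], sa[i], r[i], tg, "medium")
      }, 0)
      expect_lt(max(abs(eng - ora)), 1e-3)
    }
  }
})

test_that("forced segregation collapses to the beta-scaled unisensory density", {
  # p_same = 0: every strategy reduces to the target modality's single-cue
  # response density with bisensory noise scalings in force
  for (st in c("MS", "MA", "PM")) {
    obs <- vanilla_observer(p_same = 0, strategy = st)
    r <- seq(-20, 20, by = 4)
    eng <- bisensory_localization_density(6, -6, "high", obs, "V", r = r)
    sg <- vanilla_sigmas(obs, "high", bisensory = TRUE)
    w <- shrink_w(sg$ss, sg$sv)
    ora <- (1 - obs$context$lambda) *
      dnorm(r, w * 6, sqrt(w^2 * sg$sv^2 + obs$context$sigma_motor^2)) +
      obs$context$lambda / 90
    expect_equal(eng, ora, tolerance = 2e-3)
  }
})

test_that("strategies collapse when the causal posterior is degenerate", {
  r <- seq(-15, 15, by = 3)
  for (ps in c(0, 1)) {
    dens <- lapply(c("MS", "MA", "PM"), function(st) {
      obs <- vanilla_observer(p_same = ps, strategy = st)
      bisensory_localization_density(4, -4, "low", obs, "A", r = r)
    })
    expect_lt(max(abs(dens[[1]] - dens[[2]])), 1e-7)
    expect_lt(max(abs(dens[[2]] - dens[[3]])), 1e-7)
  }
})

test_that("response densities are normalized and BC probabilities sum to one", {
  wide <- seq(-70, 70, length.out = 2801)
  for (obs in list(vanilla_observer(), rich_observer())) {
    d_uni <- response_distribution_unisensory(8, obs, "UV", "low", r = wide)
    expect_equal(trapz(wide, d_uni$density), 1, tolerance = 1e-3)
    d_bva <- bisensory_localization_density(5, -10, "high", obs, "A", r = wide)
    expect_equal(trapz(wide, d_bva), 1, tolerance = 1e-3)
    p1 <- bc_response_probability(5, -10, "high", obs)
    # complement probability is exactly 1 - p1 by construction
    expect_true(p1 >= 0 && p1 <= 1)
  }
})

test_that("halving all grid spacings barely changes reported values", {
  # representative probabilities/densities under the richer observer
  for (st in c("MS", "PM")) {
    coarse <- rich_observer(st)
    fine <- rich_observer(st, grids = grid_spec(refine = 2))
    sv <- c(0, 8, -12)
    sa <- c(0, -10, 10)
    r <- c(2, -4, 6)
    expect_lt(max(abs(
      bc_response_probability(sv, sa, "high", coarse) -
        bc_response_probability(sv, sa, "high", fine))), 1e-3)
    expect_lt(max(abs(
      bisensory_localization_density(sv, sa, "medium", coarse, "A", r) -
        bisensory_localization_density(sv, sa, "medium", fine, "A", r))), 1e-3)
    expect_lt(max(abs(
      response_distribution_unisensory(9, coarse, "UV", "low", r = r)$density -
        response_distribution_unisensory(9, fine, "UV", "low", r = r)$density)),
      1e-3)
  }
})

test_that("heteroskedastic likelihoods use sigma at the hypothesized location", {
  # an Exp-noise observer's posterior mean is asymmetric in x around a
  # peripheral stimulus: the periphery-side hypotheses carry larger noise
  obs <- rich_observer()
  x <- c(-14, 14)
  shat <- posterior_mean_unisensory(x, obs, "V", "high")
  expect_equal(shat[1], -shat[2], tolerance = 1e-8) # symmetry about 0
  # and the shrinkage is stronger than the homoskedastic equivalent at sigma(0)
  w0 <- shrink_w(9, 1.1)
  expect_lt(abs(shat[2]), w0 * 14)
})
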