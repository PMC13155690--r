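sim_group_trials <- function(obs, n_participants = 3, uv = 120, ua = 120,
                             b = 160, bc = 160, seed = 71) {
  design <- experiment_design(n_participants = n_participants,
    trials_per_task = c(UV = uv, UA = ua, B = b, BC = bc))
  tr <- sample_experiment(design, seed = seed)
  purrr::map_dfr(seq_len(n_participants), function(p) {
    simulate_responses(tr[tr$participant == p, ], obs, seed = seed + p)
  })
}

test_that("unisensory summaries use the stated binning schemes", {
  obs <- vanilla_observer(grids = recovery_grids())
  tr <- sim_group_trials(obs)
  s_uv <- unisensory_summary(tr, "UV", "high")
  # 7 equal stimulus bins over [-20, 20]: centers at -20 + 40/14 * odd
  centers <- seq(-20 + 20 / 7, 20 - 20 / 7, length.out = 7)
  expect_equal(sort(unique(s_uv$bias$bin_center)), centers, tolerance = 1e-9)
  # UA bins are the speaker locations
  s_ua <- unisensory_summary(tr, "UA")
  expect_equal(sort(unique(s_ua$bias$bin_center)),
    c(-15, -10, -5, 0, 5, 10, 15))
  # response histograms normalize within each stimulus bin
  sums <- s_uv$distribution |>
    dplyr::group_by(bin_center) |>
    dplyr::summarise(total = sum(mean))
  expect_equal(sums$total, rep(1, 7), tolerance = 1e-9)
  # response bins are 3 degrees wide with one centered at zero
  rb <- sort(unique(s_uv$distribution$response_bin_center))
  expect_true(0 %in% rb)
  expect_equal(unique(diff(rb)), 3)
})

test_that("an unbiased responder shows near-zero bias in all bins", {
  tr <- sample_experiment(experiment_design(n_participants = 2,
    trials_per_task = c(UV = 400, UA = 400, B = 1, BC = 1)), seed = 81)
  tr <- tr[tr$task %in% c("UV", "UA"), ]
  set.seed(82)
  tr$response_loc <- ifelse(tr$task == "UV", tr$s_v, tr$s_a) + rnorm(nrow(tr), 0, 0.3)
  s <- unisensory_summary(tr, "UV", "high")
  expect_lt(max(abs(s$bias$mean)), 0.3)
  # a vanilla observer's bias slope approximates the shrinkage weight minus one
  obs <- vanilla_observer(lambda = 0, sigma_motor = 0.3,
    grids = recovery_grids())
  tr2 <- sim_group_trials(obs, n_participants = 3, uv = 2000, ua = 10, b = 10,
    bc = 10, seed = 83)
  s2 <- unisensory_summary(tr2, "UV", "high")
  slope <- stats::coef(stats::lm(mean ~ bin_center, data = s2$bias))[2]
  expect_equal(unname(slope), shrink_w(10, 2) - 1, tolerance = 0.05)
})

test_that("BC summaries stratify and report same-rates correctly", {
  obs <- vanilla_observer(grids = recovery_grids())
  tr <- sim_group_trials(obs, bc = 400)
  s <- bc_summary(tr)
  expect_setequal(unique(s$eccentricity), c("center", "periphery"))
  expect_true(all(s$mean >= 0 & s$mean <= 1))
  expect_lte(max(s$disp_bin), 9)

  # an always-"same" responder has rate one everywhere
  tr2 <- tr
  tr2$response_cat[tr2$task == "BC"] <- 1L
  s2 <- bc_summary(tr2)
  expect_equal(s2$mean, rep(1, nrow(s2)))

  # a pure-lapse group responds "same" at about one half in every stratum
  obs_lapse <- vanilla_observer(lambda = 1, grids = recovery_grids())
  tr3 <- sim_group_trials(obs_lapse, n_participants = 2, bc = 5000, seed = 91)
  s3 <- bc_summary(tr3)
  # the disparity atom at zero makes some percentile bins very small, so the
  # worst bin carries sizeable binomial noise
  expect_lt(max(abs(s3$mean - 0.5)), 0.3)
})

test_that("bisensory localization summaries show causal-inference signatures", {
  g <- recovery_grids()
  # forced fusion with constant noise: bias vs disparity is linear with slope
  # equal to the relative auditory weight (target V)
  obs_fuse <- vanilla_observer(p_same = 1, lambda = 0, sigma_s = 1e3,
    sigma_motor = 0.4, rho_a = 1, grids = g)
  tr <- sim_group_trials(obs_fuse, n_participants = 3, b = 2500, seed = 95)
  s <- bisensory_localization_summary(tr, "V")
  hi <- s[s$reliability == "high", ]
  slope <- stats::coef(stats::lm(mean ~ disparity_center, data = hi))[2]
  sv <- 2 * 1.2 # sigma0_v * beta_v
  sa <- 3 * 1.5
  w_a <- (1 / sa^2) / (1 / sv^2 + 1 / sa^2)
  expect_equal(unname(slope), w_a, tolerance = 0.08)

  # no fusion, accurate visual cue: flat bias near zero at high reliability
  obs_seg <- vanilla_observer(p_same = 0, lambda = 0, sigma_s = 1e3,
    sigma_motor = 0.4, grids = g)
  tr0 <- sim_group_trials(obs_seg, n_participants = 3, b = 3000, seed = 96)
  s0 <- bisensory_localization_summary(tr0, "V")
  expect_lt(max(abs(s0$mean[s0$reliability == "high"])), 1.2)

  # intermediate p_same: the bias flattens at large disparities instead of
  # scaling linearly (causal-inference nonlinearity)
  obs_ci <- vanilla_observer(p_same = 0.5, lambda = 0, sigma_s = 1e3,
    sigma_motor = 0.4, rho_a = 1, grids = g)
  tr5 <- sim_group_trials(obs_ci, n_participants = 3, b = 4000, seed = 97)
  bva <- tr5[tr5$task == "BV" & tr5$reliability == "high", ]
  disp <- bva$s_a - bva$s_v
  bias <- bva$response_loc - bva$s_v
  # local slope of bias vs disparity, center versus far periphery
  slope_in <- stats::coef(stats::lm(bias ~ disp, subset = abs(disp) < 8))[2]
  slope_out <- stats::coef(stats::lm(bias ~ disp, subset = abs(disp) > 22))[2]
  expect_lt(abs(slope_out), 0.5 * abs(slope_in))
})

test_that("data and model summaries run through one source-tagged code path", {
  obs <- vanilla_observer(grids = recovery_grids())
  tr <- sim_group_trials(obs, n_participants = 2)
  s_data <- unisensory_summary(tr, "UA", source = "data")
  pred <- simulate_predictive(tr, obs, n_reps = 2, seed = 5)
  s_model <- unisensory_summary(pred, "UA", source = "model")
  expect_equal(names(s_data$bias), names(s_model$bias))
  expect_equal(unique(s_data$bias$source), "data")
  expect_equal(unique(s_model$bias$source), "model")
  # same bin structure, comparable values
  expect_equal(s_data$bias$bin_center, s_model$bias$bin_center)
})

test_that("participant-level t helper matches stats::t.test", {
  x <- c(1.2, 1.4, 1.1, 1.5, 1.3)
  out <- t_test_participants(x, mu = 1, alternative = "greater")
  ref <- t.test(x, mu = 1, alternative = "greater")
  expect_equal(out$statistic, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
})
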