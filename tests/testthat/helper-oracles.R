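# Independent conjugate-Gaussian oracles for the vanilla observer
# (constant noise + single-Gaussian prior). Derived from closed forms before
# the engine was built; they never call the engine's quadrature machinery.
# Notation: ss = prior SD, sv/sa = effective visual/auditory noise SDs,
# sm = motor SD, rho = auditory recalibration gain, ps = p(C = 1).

# Effective noise SDs of a vanilla observer for a given task context.
vanilla_sigmas <- function(obs, reliability = "high", bisensory = FALSE) {
  ctx <- obs$context
  mult <- switch(reliability, high = 1, medium = ctx$alpha_med,
    low = ctx$alpha_low)
  list(
    sv = obs$noise_v$params$sigma0 * mult * (if (bisensory) ctx$beta_v else 1),
    sa = obs$noise_a$params$sigma0 * (if (bisensory) ctx$beta_a else 1),
    ss = obs$prior$params$sigma_s
  )
}

# UV/UA response density: r | s is Gaussian with shrunk mean, plus lapse.
oracle_unisensory_density <- function(obs, modality, s, r, reliability = "high") {
  sg <- vanilla_sigmas(obs, reliability)
  ctx <- obs$context
  sig <- if (modality == "V") sg$sv else sg$sa
  gain <- if (modality == "A") ctx$rho_a else 1
  w <- shrink_w(sg$ss, sig)
  (1 - ctx$lambda) * dnorm(r, w * gain * s, sqrt(w^2 * gain^2 * sig^2 +
    ctx$sigma_motor^2)) + ctx$lambda / 90
}

# Common-cause evidence and causal posterior at internal measurements (xv, ma).
oracle_pc1 <- function(obs, xv, ma, reliability = "high") {
  sg <- vanilla_sigmas(obs, reliability, bisensory = TRUE)
  ps <- obs$context$p_same
  l1 <- dnorm(xv - ma, 0, sqrt(sg$sv^2 + sg$sa^2)) *
    dnorm((xv * sg$sa^2 + ma * sg$sv^2) / (sg$sv^2 + sg$sa^2), 0,
      sqrt(sg$sv^2 * sg$sa^2 / (sg$sv^2 + sg$sa^2) + sg$ss^2))
  l2 <- dnorm(xv, 0, sqrt(sg$sv^2 + sg$ss^2)) *
    dnorm(ma, 0, sqrt(sg$sa^2 + sg$ss^2))
  ps * l1 / (ps * l1 + (1 - ps) * l2)
}

oracle_fused_mean <- function(obs, xv, ma, reliability = "high") {
  sg <- vanilla_sigmas(obs, reliability, bisensory = TRUE)
  (xv / sg$sv^2 + ma / sg$sa^2) / (1 / sg$sv^2 + 1 / sg$sa^2 + 1 / sg$ss^2)
}

oracle_single_mean <- function(obs, x, target, reliability = "high") {
  sg <- vanilla_sigmas(obs, reliability, bisensory = TRUE)
  sig <- if (target == "V") sg$sv else sg$sa
  shrink_w(sg$ss, sig) * x
}

# BC "same" probability by quadrature over the generative measurements with
# closed-form posteriors: smooth (auditory) direction by a moderately fine
# grid, discontinuous (visual) direction by a very fine grid so the indicator
# is resolved.
oracle_bc_probability <- function(obs, sv, sa, reliability = "high",
                                  nxa = 601, nxv = 6001) {
  sg <- vanilla_sigmas(obs, reliability, bisensory = TRUE)
  ctx <- obs$context
  ua <- seq(-6, 6, length.out = nxa)
  wa <- dnorm(ua)
  wa <- wa / sum(wa)
  uv <- seq(-6, 6, length.out = nxv)
  wv <- dnorm(uv)
  wv <- wv / sum(wv)
  xvn <- sv + uv * sg$sv
  p1 <- 0
  for (k in seq_len(nxa)) {
    man <- ctx$rho_a * (sa + ua[k] * sg$sa)
    p <- oracle_pc1(obs, xvn, man, reliability)
    f <- if (obs$strategy == "PM") p else as.numeric(p >= 0.5)
    p1 <- p1 + wa[k] * sum(wv * f)
  }
  ctx$lambda / 2 + (1 - ctx$lambda) * p1
}

# BV/BA response density at r by the same two-resolution quadrature.
oracle_bva_density <- function(obs, sv, sa, r, target, reliability = "high",
                               nxa = 401, nxv = 4001) {
  sg <- vanilla_sigmas(obs, reliability, bisensory = TRUE)
  ctx <- obs$context
  ua <- seq(-6, 6, length.out = nxa)
  wa <- dnorm(ua)
  wa <- wa / sum(wa)
  uv <- seq(-6, 6, length.out = nxv)
  wv <- dnorm(uv)
  wv <- wv / sum(wv)
  xvn <- sv + uv * sg$sv
  dens <- 0
  for (k in seq_len(nxa)) {
    man <- ctx$rho_a * (sa + ua[k] * sg$sa)
    p <- oracle_pc1(obs, xvn, man, reliability)
    s1 <- oracle_fused_mean(obs, xvn, man, reliability)
    s2 <- if (target == "V") oracle_single_mean(obs, xvn, "V", reliability)
      else oracle_single_mean(obs, man, "A", reliability)
    q <- switch(obs$strategy,
      MS = dnorm(r, ifelse(p >= 0.5, s1, s2), ctx$sigma_motor),
      MA = dnorm(r, p * s1 + (1 - p) * s2, ctx$sigma_motor),
      PM = p * dnorm(r, s1, ctx$sigma_motor) +
        (1 - p) * dnorm(r, s2, ctx$sigma_motor))
    dens <- dens + wa[k] * sum(wv * q)
  }
  (1 - ctx$lambda) * dens + ctx$lambda / 90
}

# Chi-square goodness of fit of observed counts against known bin
# probabilities, pooling bins with small expectation.
chisq_gof <- function(counts, probs, min_expected = 5) {
  n <- sum(counts)
  expected <- probs * n
  ord <- order(expected)
  counts <- counts[ord]
  expected <- expected[ord]
  # pool from the smallest expectation upward
  while (length(expected) > 2 && expected[1] < min_expected) {
    expected[2] <- expected[2] + expected[1]
    counts[2] <- counts[2] + counts[1]
    expected <- expected[-1]
    counts <- counts[-1]
  }
  stat <- sum((counts - expected)^2 / expected)
  df <- length(expected) - 1
  list(statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
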