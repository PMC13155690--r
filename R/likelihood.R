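# Likelihood engine: exact-model response probabilities for all five tasks,
# computed by trapezoidal quadrature on the grids of the observer's grid_spec.
#
# Conventions used throughout:
# * sigma(s) inside likelihood integrands is evaluated at the hypothesized s
#   (true heteroskedastic likelihood).
# * the generative auditory measurement is x_A ~ N(s_A, sigma_A^2(s_A)); the
#   internal measurement fed to every inference formula is m_A = rho_A * x_A,
#   never corrected downstream.
# * the motor-noise Gaussian is untruncated; lapse mass is uniform on the
#   response range.
# * ties of the causal posterior at exactly 0.5 count as C = 1.

# Internal measurements are capped at +/- MEAS_CAP degrees: posterior
# estimates and causal posteriors saturate far outside the stimulus support,
# so clamping leaves results unchanged for plausible noise levels while
# bounding the cost of tabulated fields when the optimizer visits extreme
# noise parameters.
MEAS_CAP <- 180

clamp_meas <- function(x) {
  x[x > MEAS_CAP] <- MEAS_CAP
  x[x < -MEAS_CAP] <- -MEAS_CAP
  x
}

# --- low-level quadrature primitives -----------------------------------------

# Gaussian likelihood matrix over the stimulus grid: rows follow s_grid,
# columns the measurement vector x. sig is sigma(s) on s_grid.
lik_matrix <- function(s_grid, sig, x) {
  d <- outer(-s_grid, x, "+") # [j, i] = x_i - s_j
  exp(-0.5 * (d / sig)^2) / (sqrt(2 * pi) * sig)
}

# Posterior mean of s for each internal measurement x (direct quadrature,
# chunked to bound memory). pw = prior density * trapezoid weights on s_grid.
post_mean_direct <- function(x, s_grid, sig, pw) {
  out <- cpp_post_mean(x, s_grid, sig, pw)
  edge <- max(abs(s_grid))
  if (any(abs(out) >= edge - 1e-12)) {
    warn("Degenerate posterior (zero mass) for some measurements; estimates clamped to the support edge.",
      .frequency = "once", .frequency_id = "causalobs_degenerate_posterior")
  }
  out
}

# Tabulated posterior mean on an absolute grid (multiples of `spacing`), so
# cached group-level tables and per-trial rebuilds share identical nodes.
post_mean_table <- function(range, spacing, s_grid, sig, pw) {
  lo <- floor(range[1] / spacing) - 1
  hi <- ceiling(range[2] / spacing) + 1
  xg <- (lo:hi) * spacing
  list(x = xg, shat = post_mean_direct(xg, s_grid, sig, pw))
}

# Normalized quadrature nodes/weights for integrating over a Gaussian
# measurement distribution: x = s + u * sigma, weights ~ phi(u) du.
measurement_nodes <- function(n, span) {
  u <- seq(-span, span, length.out = n)
  w <- dnorm(u) * trapz_weights(u)
  list(u = u, w = w / sum(w))
}

# --- unisensory operations ---------------------------------------------------

#' Posterior mean estimate from a single noisy measurement
#'
#' Computes `shat = E[s | x]` under the observer's prior and the modality's
#' (context-scaled) sensory noise, by trapezoidal quadrature on the stimulus
#' grid. For audition, `x` is taken to be the already-recalibrated internal
#' measurement.
#'
#' @param x Internal measurements (deg); vectorized.
#' @param observer An [observer_model()].
#' @param modality `"V"` or `"A"`.
#' @param reliability Visual reliability level (ignored for audition).
#' @param bisensory Whether bisensory noise scalings apply.
#' @return Posterior mean estimates (deg).
#' @export
posterior_mean_unisensory <- function(x, observer, modality = "V",
                                      reliability = NULL, bisensory = FALSE) {
  sig <- sigma_on_grid(observer, modality, reliability, bisensory)
  post_mean_direct(x, observer$s_grid, sig, observer$prior_w)
}

# Shared unisensory density computation: density of observed responses r for
# stimuli s (same length), one task/reliability group at a time.
unisensory_density_group <- function(observer, modality, s, r, reliability = NULL) {
  g <- observer$grids
  ctx <- observer$context
  sig_s <- sigma_at(observer, modality, s, reliability, bisensory = FALSE)
  nodes <- measurement_nodes(g$x_points, g$x_span)
  gain <- if (modality == "A") ctx$rho_a else 1
  sig_grid <- sigma_on_grid(observer, modality, reliability, bisensory = FALSE)
  # posterior-mean table spacing adapts to the central noise level (the
  # estimate varies on the noise scale when the likelihood is wide), and the
  # table spans measurement nodes out to 4 noise SDs; the few outermost nodes
  # (relative mass ~6e-5) are clamped to the table edge.
  spacing <- max(g$shat_spacing, gain * min(sig_grid) / 6)
  smax <- max(sig_s)
  tab_range <- clamp_meas(gain * c(min(s) - 4 * smax, max(s) + 4 * smax))
  tab <- post_mean_table(tab_range, spacing, observer$s_grid, sig_grid,
    observer$prior_w)
  motor_part <- cpp_unisensory_density(s, r, sig_s, nodes$u, nodes$w, gain,
    MEAS_CAP, tab$x[1], spacing, tab$shat, ctx$sigma_motor)
  lapse_part <- (abs(r) <= RANGE_HALF) / RANGE_WIDTH
  (1 - ctx$lambda) * motor_part + ctx$lambda * lapse_part
}

# Content-addressed cache of group-level density vectors: the key hashes every
# numerical input of the computation, so a hit is exact. This pays off in
# finite-difference gradients, where most parameter perturbations leave most
# task/reliability groups untouched.
.group_cache <- new.env(parent = emptyenv())

group_cache_get <- function(key, fn) {
  hit <- .group_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(ls(.group_cache)) >= 512) {
    rm(list = ls(.group_cache), envir = .group_cache)
  }
  val <- fn()
  .group_cache[[key]] <- val
  val
}

unisensory_group_cached <- function(observer, modality, s, r, reliability = NULL) {
  ctx <- observer$context
  key <- rlang::hash(list(
    "uni", modality, reliability,
    sigma_on_grid(observer, modality, reliability, bisensory = FALSE),
    observer$prior_w, ctx$rho_a, ctx$lambda, ctx$sigma_motor,
    unclass(observer$grids), s, r
  ))
  group_cache_get(key, function() {
    unisensory_density_group(observer, modality, s, r, reliability)
  })
}

#' Response distribution for a unisensory localization trial
#'
#' `p(r | s)` for a UV or UA trial: the posterior-mean estimate of the noisy
#' measurement (recalibrated by `rho_a` on the auditory path) corrupted by
#' Gaussian motor noise, mixed with a uniform lapse over the response range.
#'
#' @param s True stimulus location (single value).
#' @param observer An [observer_model()].
#' @param task `"UV"` or `"UA"`.
#' @param reliability Visual reliability level (UV only).
#' @param r Response locations at which to evaluate the density; defaults to a
#'   uniform response grid over the support.
#' @return A tibble with columns `r` and `density`.
#' @export
response_distribution_unisensory <- function(s, observer, task = c("UV", "UA"),
                                             reliability = NULL, r = NULL) {
  task <- match.arg(task)
  if (task == "UV" && (is.null(reliability) || is.na(reliability))) {
    abort("UV evaluation requires a visual reliability level.")
  }
  if (task == "UA" && !is.null(reliability) && !is.na(reliability)) {
    abort("UA trials carry no visual reliability level.")
  }
  if (is.null(r)) {
    r <- seq(observer$grids$support[1], observer$grids$support[2],
      length.out = observer$grids$r_points)
  }
  modality <- if (task == "UV") "V" else "A"
  dens <- unisensory_density_group(observer, modality, rep(s, length(r)), r,
    reliability)
  tibble::tibble(r = r, density = dens)
}

# --- bisensory measurement-level operations ----------------------------------

#' Posterior probability of a common cause
#'
#' `p(C = 1 | x_V, x_A)` from the two internal measurements, with the
#' common-cause evidence `L1 = integral p(x_V|s) p(x_A|s) p(s) ds` and the
#' independent-cause evidence equal to the product of the single-cue marginals.
#' `x_a` is the already-recalibrated internal auditory measurement; bisensory
#' noise scalings are in force.
#'
#' @param x_v,x_a Internal measurements (deg); vectorized in parallel.
#' @param observer An [observer_model()].
#' @param reliability Visual reliability level.
#' @return Posterior probabilities of `C = 1`.
#' @export
causal_posterior <- function(x_v, x_a, observer, reliability = "high") {
  stopifnot(length(x_v) == length(x_a))
  sv <- sigma_on_grid(observer, "V", reliability, bisensory = TRUE)
  sa <- sigma_on_grid(observer, "A", NULL, bisensory = TRUE)
  pw <- observer$prior_w
  ps <- observer$context$p_same
  out <- numeric(length(x_v))
  chunk <- 2048L
  for (idx in split(seq_along(x_v), ceiling(seq_along(x_v) / chunk))) {
    mv_mat <- lik_matrix(observer$s_grid, sv, x_v[idx])
    ma_mat <- lik_matrix(observer$s_grid, sa, x_a[idx])
    l1 <- crossprod(mv_mat * ma_mat, pw)
    l2 <- crossprod(mv_mat, pw) * crossprod(ma_mat, pw)
    den <- ps * l1 + (1 - ps) * l2
    if (any(den <= 0)) abort("Zero total evidence in causal posterior.")
    out[idx] <- ps * l1 / den
  }
  out
}

#' Posterior mean location estimates under both causal hypotheses
#'
#' `shat_{C=1}` from the fused posterior (both measurements, shared source) and
#' `shat_{C=2}` from the target modality's single-cue posterior. `x_a` is the
#' internal (recalibrated) auditory measurement.
#'
#' @inheritParams causal_posterior
#' @param target Reported modality, `"V"` or `"A"`.
#' @return A tibble with columns `shat_c1` and `shat_c2`.
#' @export
posterior_means_bisensory <- function(x_v, x_a, observer, target = c("V", "A"),
                                      reliability = "high") {
  target <- match.arg(target)
  stopifnot(length(x_v) == length(x_a))
  s <- observer$s_grid
  sv <- sigma_on_grid(observer, "V", reliability, bisensory = TRUE)
  sa <- sigma_on_grid(observer, "A", NULL, bisensory = TRUE)
  pw <- observer$prior_w
  mv_mat <- lik_matrix(s, sv, x_v)
  ma_mat <- lik_matrix(s, sa, x_a)
  joint <- mv_mat * ma_mat
  l1 <- crossprod(joint, pw)
  if (any(l1 <= 0)) abort("Zero total evidence in fused posterior.")
  shat_c1 <- crossprod(joint, pw * s) / l1
  tgt_mat <- if (target == "V") mv_mat else ma_mat
  shat_c2 <- crossprod(tgt_mat, pw * s) / crossprod(tgt_mat, pw)
  tibble::tibble(shat_c1 = as.vector(shat_c1), shat_c2 = as.vector(shat_c2))
}

# --- bisensory fields (cached per reliability) -------------------------------

# Tabulate pc1, fused posterior mean and the single-cue posterior means on an
# absolute internal-measurement grid. Grid nodes are multiples of the spacing,
# so per-trial rebuilds coincide exactly with cached group-level fields.
bis_fields <- function(observer, reliability, xv_range, ma_range) {
  s <- observer$s_grid
  sv <- sigma_on_grid(observer, "V", reliability, bisensory = TRUE)
  sa <- sigma_on_grid(observer, "A", NULL, bisensory = TRUE)
  pw <- observer$prior_w
  ps <- observer$context$p_same
  h <- min(observer$grids$field_spacing,
    max(sqrt(sv[which.min(abs(s))]^2 + sa[which.min(abs(s))]^2) / 10, 0.05))
  axis <- function(rng) (floor(rng[1] / h - 1):ceiling(rng[2] / h + 1)) * h
  xv <- axis(xv_range)
  ma <- axis(ma_range)
  v_mat <- t(lik_matrix(s, sv, xv))      # nv x ns
  a_mat <- t(lik_matrix(s, sa, ma))      # na x ns
  at_w <- t(a_mat) * pw                  # ns x na
  l1 <- v_mat %*% at_w
  n1 <- v_mat %*% (at_w * s)
  mv <- as.vector(v_mat %*% pw)
  mam <- as.vector(a_mat %*% pw)
  shat2_v <- as.vector(v_mat %*% (pw * s)) / mv
  shat2_a <- as.vector(a_mat %*% (pw * s)) / mam
  den <- ps * l1 + (1 - ps) * outer(mv, mam)
  pc1 <- ps * l1 / den
  pc1[den <= 0] <- ps # zero-evidence corners: prior fallback
  shat1 <- n1 / l1
  shat1[l1 <= 0] <- 0
  list(xv = xv, ma = ma, h = h, pc1 = pc1, shat1 = shat1,
    shat2_v = shat2_v, shat2_a = shat2_a)
}

# Quadrature node layout for a chunk of bisensory trials: per trial, an
# x_points_2d x x_points_2d grid of (x_V, raw x_A) measurement nodes. The MS
# localization kernel is discontinuous across the decision boundary, so that
# path requests doubled node density (`dense`) to keep the O(h) cell error
# small; the BC indicator is handled exactly and needs no densification.
bis_nodes <- function(observer, s_v, s_a, reliability, dense = FALSE) {
  g <- observer$grids
  n_nodes <- if (dense) 2L * (g$x_points_2d - 1L) + 1L else g$x_points_2d
  nodes <- measurement_nodes(n_nodes, g$x_span)
  sig_v <- sigma_at(observer, "V", s_v, reliability, bisensory = TRUE)
  sig_a <- sigma_at(observer, "A", s_a, NULL, bisensory = TRUE)
  list(
    xv = clamp_meas(outer(s_v, rep(1, length(nodes$u))) + outer(sig_v, nodes$u)),
    xa = outer(s_a, rep(1, length(nodes$u))) + outer(sig_a, nodes$u), # n x nb
    w = nodes$w
  )
}

# Evaluate BC response probabilities for one reliability group given
# precomputed fields. The PM path integrates the (smooth) causal posterior by
# quadrature; the MS/MA path integrates the indicator pc1 >= 0.5 exactly in
# the visual-measurement direction (root interpolation of the decision
# boundary on the field grid + Gaussian mass via pnorm), which converges
# stably despite the discontinuity.
bc_prob_group <- function(observer, fields, s_v, s_a) {
  ctx <- observer$context
  nd <- bis_nodes(observer, s_v, s_a, attr(fields, "reliability"))
  ma <- clamp_meas(apply_recalibration(nd$xa, ctx$rho_a))
  nb <- length(nd$w)
  n <- length(s_v)
  out <- numeric(n)
  if (observer$strategy == "PM") {
    w2 <- as.vector(outer(nd$w, nd$w)) # [i (xv), k (xa)] flattened
    for (idx in split(seq_len(n), ceiling(seq_len(n) / 256L))) {
      m <- length(idx)
      xq <- nd$xv[idx, rep(seq_len(nb), times = nb), drop = FALSE]
      yq <- ma[idx, rep(seq_len(nb), each = nb), drop = FALSE]
      p <- interp_bilinear(fields$pc1, fields$xv[1], fields$h, fields$ma[1],
        fields$h, as.vector(xq), as.vector(yq), clamp = FALSE)
      out[idx] <- matrix(p, nrow = m) %*% w2
    }
  } else {
    sig_v <- sigma_at(observer, "V", s_v, attr(fields, "reliability"),
      bisensory = TRUE)
    xg <- fields$xv
    nv <- length(xg)
    na_grid <- length(fields$ma)
    for (t in seq_len(n)) {
      # pc1 along the xv axis at each auditory node (linear in ma)
      v <- pmin(pmax((ma[t, ] - fields$ma[1]) / fields$h, 0), na_grid - 1 - 1e-9)
      j <- floor(v)
      fv <- rep(v - j, each = nv)
      j <- j + 1L
      d <- fields$pc1[, j] * (1 - fv) + fields$pc1[, j + 1L] * fv - 0.5
      B <- d >= 0 # ties at 0.5 count as C = 1
      cdf <- pnorm(xg, s_v[t], sig_v[t])
      cell <- diff(cdf)
      inside <- B[-nv, , drop = FALSE] & B[-1, , drop = FALSE]
      mass <- colSums(inside * cell) +
        B[1, ] * cdf[1] + B[nv, ] * (1 - cdf[nv])
      crossing <- which(B[-nv, , drop = FALSE] != B[-1, , drop = FALSE])
      if (length(crossing) > 0) {
        i <- (crossing - 1) %% (nv - 1) + 1
        k <- (crossing - 1) %/% (nv - 1) + 1
        di <- d[cbind(i, k)]
        dip <- d[cbind(i + 1L, k)]
        root <- xg[i] + fields$h * di / (di - dip)
        root_cdf <- pnorm(root, s_v[t], sig_v[t])
        # B[i] true: mass from x_i to the root; else from the root to x_{i+1}
        part <- ifelse(B[cbind(i, k)], root_cdf - cdf[i], cdf[i + 1L] - root_cdf)
        add <- numeric(nb)
        agg <- tapply(part, k, sum)
        add[as.integer(names(agg))] <- agg
        mass <- mass + add
      }
      out[t] <- sum(nd$w * mass)
    }
  }
  ctx$lambda / 2 + (1 - ctx$lambda) * out
}

bva_density_group <- function(observer, fields, s_v, s_a, r, target) {
  ctx <- observer$context
  rel <- attr(fields, "reliability")
  nd <- bis_nodes(observer, s_v, s_a, rel, dense = observer$strategy == "MS")
  ma <- clamp_meas(apply_recalibration(nd$xa, ctx$rho_a))
  nb <- length(nd$w)
  n <- length(s_v)
  out <- numeric(n)
  w2 <- as.vector(outer(nd$w, nd$w))
  for (idx in split(seq_len(n), ceiling(seq_len(n) / 128L))) {
    m <- length(idx)
    xq <- as.vector(nd$xv[idx, rep(seq_len(nb), times = nb), drop = FALSE])
    yq <- as.vector(ma[idx, rep(seq_len(nb), each = nb), drop = FALSE])
    p <- interp_bilinear(fields$pc1, fields$xv[1], fields$h, fields$ma[1],
      fields$h, xq, yq, clamp = FALSE)
    s1 <- interp_bilinear(fields$shat1, fields$xv[1], fields$h, fields$ma[1],
      fields$h, xq, yq, clamp = FALSE)
    s2 <- if (target == "V") {
      interp_linear(fields$xv, fields$shat2_v, xq)
    } else {
      interp_linear(fields$ma, fields$shat2_a, yq)
    }
    rr <- rep(r[idx], times = nb * nb)
    q <- switch(observer$strategy,
      MS = {
        mu <- s2
        sel <- p >= 0.5
        mu[sel] <- s1[sel]
        dnorm(rr, mu, ctx$sigma_motor)
      },
      MA = dnorm(rr, p * s1 + (1 - p) * s2, ctx$sigma_motor),
      PM = p * dnorm(rr, s1, ctx$sigma_motor) +
        (1 - p) * dnorm(rr, s2, ctx$sigma_motor)
    )
    out[idx] <- matrix(q, nrow = m) %*% w2
  }
  (1 - ctx$lambda) * out + ctx$lambda * (abs(r) <= RANGE_HALF) / RANGE_WIDTH
}

# Build fields covering the quadrature nodes of a trial group.
fields_for_group <- function(observer, s_v, s_a, reliability) {
  nd <- bis_nodes(observer, s_v, s_a, reliability)
  ma <- clamp_meas(apply_recalibration(nd$xa, observer$context$rho_a))
  f <- bis_fields(observer, reliability, range(nd$xv), range(ma))
  attr(f, "reliability") <- reliability
  f
}

#' Probability of a "same source" judgment in the BC task
#'
#' `p(r_C = 1 | s_V, s_A)`: the causal posterior is integrated over the latent
#' noisy measurements — through the indicator `p(C=1|x_V,x_A) >= 0.5` for the
#' MS/MA strategies (equivalent for BC) or through the posterior probability
#' itself for PM — and mixed with a fair categorical lapse.
#'
#' @param s_v,s_a True stimulus locations (deg); vectorized in parallel.
#' @param reliability Visual reliability level (single value per call).
#' @param observer An [observer_model()].
#' @return Probabilities of responding "same".
#' @export
bc_response_probability <- function(s_v, s_a, reliability, observer) {
  stopifnot(length(s_v) == length(s_a))
  fields <- fields_for_group(observer, s_v, s_a, reliability)
  bc_prob_group(observer, fields, s_v, s_a)
}

#' Response density for a bisensory localization trial
#'
#' `p(r | s_V, s_A)` for BV/BA trials: the strategy-specific response kernel
#' (Gaussian at the selected estimate for MS, at the posterior-weighted
#' estimate for MA, or a two-component mixture for PM) integrated over the
#' latent measurements, mixed with a uniform lapse over the response range.
#'
#' @inheritParams bc_response_probability
#' @param target Reported modality, `"V"` (BV) or `"A"` (BA).
#' @param r Observed responses, one per trial; or, when a single trial is
#'   given, a vector of evaluation points.
#' @return Densities at `r`.
#' @export
bisensory_localization_density <- function(s_v, s_a, reliability, observer,
                                           target = c("V", "A"), r) {
  target <- match.arg(target)
  stopifnot(length(s_v) == length(s_a))
  if (length(s_v) == 1 && length(r) > 1) {
    s_v <- rep(s_v, length(r))
    s_a <- rep(s_a, length(r))
  }
  stopifnot(length(r) == length(s_v))
  fields <- fields_for_group(observer, s_v, s_a, reliability)
  bva_density_group(observer, fields, s_v, s_a, r, target)
}

# --- trial-table likelihood --------------------------------------------------

# Per-trial response probability/density for a responded trial table.
# use_cache = FALSE rebuilds all tables and fields per trial (identical nodes,
# so results match to rounding); used to validate the caching logic.
trial_likelihood <- function(observer, trials, use_cache = TRUE) {
  validate_trials(trials)
  lik <- numeric(nrow(trials))
  for (task in intersect(TASKS, unique(trials$task))) {
    if (task %in% c("UV", "UA")) {
      modality <- if (task == "UV") "V" else "A"
      rels <- if (task == "UV") RELIABILITIES else NA_character_
      for (rel in rels) {
        rows <- which(trials$task == task &
          (is.na(rel) | (!is.na(trials$reliability) & trials$reliability == rel)))
        if (length(rows) == 0) next
        s <- if (task == "UV") trials$s_v[rows] else trials$s_a[rows]
        r <- trials$response_loc[rows]
        if (any(is.na(r))) abort(sprintf("Unresponded %s trials.", task))
        rel_arg <- if (task == "UV") rel else NULL
        if (use_cache) {
          lik[rows] <- unisensory_group_cached(observer, modality, s, r, rel_arg)
        } else {
          for (k in seq_along(rows)) {
            lik[rows[k]] <- unisensory_density_group(observer, modality, s[k],
              r[k], rel_arg)
          }
        }
      }
    } else {
      for (rel in RELIABILITIES) {
        rows <- which(trials$task == task & trials$reliability == rel)
        if (length(rows) == 0) next
        s_v <- trials$s_v[rows]
        s_a <- trials$s_a[rows]
        if (task == "BC") {
          rc <- trials$response_cat[rows]
          if (any(is.na(rc))) abort("Unresponded BC trials.")
          eval_bc <- function(sv, sa) bc_response_probability(sv, sa, rel, observer)
          p1 <- if (use_cache) {
            # dedupe identical stimulus pairs (half the BC trials share a source)
            key <- paste(s_v, s_a)
            uniq <- which(!duplicated(key))
            eval_bc(s_v[uniq], s_a[uniq])[match(key, key[uniq])]
          } else {
            vapply(seq_along(rows), function(k) eval_bc(s_v[k], s_a[k]), 0)
          }
          lik[rows] <- ifelse(rc == 1L, p1, 1 - p1)
        } else {
          r <- trials$response_loc[rows]
          if (any(is.na(r))) abort(sprintf("Unresponded %s trials.", task))
          target <- if (task == "BV") "V" else "A"
          eval_bva <- function(sv, sa, rr) {
            bisensory_localization_density(sv, sa, rel, observer, target, rr)
          }
          lik[rows] <- if (use_cache) eval_bva(s_v, s_a, r) else
            vapply(seq_along(rows), function(k) eval_bva(s_v[k], s_a[k], r[k]), 0)
        }
      }
    }
  }
  lik
}
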