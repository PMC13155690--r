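# Sensory-noise function families sigma(s): SD of the Gaussian measurement
# distribution as a function of true stimulus location. All shapes are
# symmetric in s and non-decreasing in |s|.

new_noise <- function(family, params, base_fun, modality) {
  modality <- match.arg(modality, c("V", "A"))
  structure(
    list(family = family, params = params, base = base_fun, modality = modality),
    class = c(paste0("noise_", tolower(family)), "noise_model")
  )
}

#' Sensory-noise function families
#'
#' * `noise_const()`: homoskedastic noise, `sigma(s) = sigma0`.
#' * `noise_exp()`: heteroskedastic exponential noise,
#'   `sigma(s) = sigma0 + k1 * (1 - exp(-k2 * |s|))`, which dips at the
#'   straight-ahead direction and plateaus at `sigma0 + k1` in the periphery.
#'
#' The base shape describes the high-reliability unisensory condition of its
#' modality; reliability multipliers (`alpha_med`, `alpha_low`, vision only)
#' and unisensory-to-bisensory multipliers (`beta_v`, `beta_a`) are applied by
#' [noise_sigma()].
#'
#' @param sigma0 Baseline SD at `s = 0` (deg), positive.
#' @param k1 Plateau rise (deg), non-negative.
#' @param k2 Spatial rate (1/deg), positive.
#' @param modality `"V"` or `"A"`.
#' @return A `noise_model` object.
#' @name noise_families
#' @examples
#' nm <- noise_exp(1, 3, 0.3)
#' noise_sigma(nm, c(0, 10, -10))
NULL

#' @rdname noise_families
#' @export
noise_const <- function(sigma0, modality = "V") {
  stopifnot(sigma0 > 0)
  new_noise("Const", list(sigma0 = sigma0), function(s) rep(sigma0, length(s)),
    modality)
}

#' @rdname noise_families
#' @export
noise_exp <- function(sigma0, k1, k2, modality = "V") {
  stopifnot(sigma0 > 0, k1 >= 0, k2 > 0)
  new_noise("Exp", list(sigma0 = sigma0, k1 = k1, k2 = k2),
    function(s) sigma0 + k1 * (1 - exp(-k2 * abs(s))), modality)
}

#' Build a semiparametric (pivot-based) noise shape
#'
#' `sigma` at the first pivot is `exp(theta[1])`; each successive pivot adds
#' `exp(theta[j])`, so the shape is positive and monotonically non-decreasing
#' in `|s|` by construction. Values between pivots come from monotone cubic
#' interpolation; negative locations by mirror symmetry.
#'
#' @param theta 12 finite log-values (base value plus 11 log-increments).
#' @param pivots Pivot locations, by default [pivot_grid()].
#' @param modality `"V"` or `"A"`.
#' @return A `noise_model` object.
#' @export
#' @examples
#' nm <- noise_semiparametric(c(log(2), rep(log(1e-6), 11)))
#' noise_sigma(nm, c(0, 20)) # effectively flat at 2 degrees
noise_semiparametric <- function(theta, pivots = pivot_grid(), modality = "V") {
  if (length(theta) != length(pivots)) {
    abort(sprintf("`theta` must have %d values (base + increments).", length(pivots)))
  }
  if (any(!is.finite(theta))) abort("`theta` must be finite.")
  vals <- cumsum(exp(pmax(theta, LOG_INCREMENT_FLOOR)))
  interp <- splinefun(pivots, vals, method = "hyman")
  nm <- new_noise("SemiparametricPivot", list(theta = theta, pivots = pivots),
    function(s) interp(pmin(abs(s), max(pivots))), modality)
  nm$pivot_values <- vals
  nm
}

#' Evaluate a sensory-noise function
#'
#' Evaluates the base shape at `|s|` and applies the context scalings: the
#' visual reliability multiplier (`alpha_med` or `alpha_low`) for medium/low
#' reliability trials, and the modality's unisensory-to-bisensory multiplier
#' (`beta_v` or `beta_a`) when `bisensory = TRUE`. Reliability scaling applies
#' to vision only; passing a reliability level for an auditory noise model is
#' an error.
#'
#' @param noise A `noise_model` object.
#' @param s Stimulus locations (deg).
#' @param reliability `NULL` (or `"high"`), `"medium"`, or `"low"`.
#' @param context A [context_params()] object.
#' @param bisensory Whether the trial is bisensory.
#' @return Noise SDs in degrees (same length as `s`).
#' @export
noise_sigma <- function(noise, s, reliability = NULL, context = context_params(),
                        bisensory = FALSE) {
  stopifnot(inherits(noise, "noise_model"))
  mult <- 1
  if (!is.null(reliability) && !is.na(reliability)) {
    if (noise$modality == "A") {
      abort("Reliability scaling applies to visual noise only.")
    }
    reliability <- match.arg(reliability, RELIABILITIES)
    mult <- switch(reliability, high = 1, medium = context$alpha_med,
      low = context$alpha_low)
  }
  if (bisensory) {
    mult <- mult * if (noise$modality == "V") context$beta_v else context$beta_a
  }
  noise$base(s) * mult
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model>", x$family, sprintf("(modality %s)\n", x$modality))
  scalars <- Filter(function(p) is.numeric(p) && length(p) == 1, x$params)
  if (length(scalars) > 0) {
    cat(" ", paste(names(scalars), signif(unlist(scalars), 4), sep = "=",
      collapse = ", "), "\n")
  }
  invisible(x)
}

#' Context parameters of an observer model
#'
#' Scalar parameters shared across the shape components: visual reliability
#' noise multipliers, unisensory-to-bisensory noise multipliers, the auditory
#' range recalibration gain, the prior probability of a common cause, the lapse
#' rate, the motor noise SD, and the prior exponent used by lifted fits.
#'
#' @param alpha_med,alpha_low Visual noise multipliers for medium-/low-
#'   reliability trials (unitless, positive).
#' @param beta_v,beta_a Unisensory-to-bisensory noise multipliers (unitless,
#'   positive).
#' @param rho_a Auditory range recalibration gain applied to noisy auditory
#'   measurements (unitless; 1 disables recalibration, 4/3 is a full remapping
#'   of the auditory range onto the visual range).
#' @param p_same Prior probability that the two bisensory stimuli share a
#'   source, in `[0, 1]`.
#' @param lambda Lapse rate in `[0, 1]`.
#' @param sigma_motor Motor noise SD (deg), positive.
#' @param gamma Prior exponent (lifted models only), non-negative.
#' @return An object of class `context_params`.
#' @export
context_params <- function(alpha_med = 1, alpha_low = 1, beta_v = 1, beta_a = 1,
                           rho_a = 1, p_same = 0.5, lambda = 0,
                           sigma_motor = 1, gamma = 1) {
  stopifnot(alpha_med > 0, alpha_low > 0, beta_v > 0, beta_a > 0, rho_a > 0,
    sigma_motor > 0, gamma >= 0)
  assert_scalar_prob(p_same, "p_same")
  assert_scalar_prob(lambda, "lambda")
  structure(
    list(alpha_med = alpha_med, alpha_low = alpha_low, beta_v = beta_v,
      beta_a = beta_a, rho_a = rho_a, p_same = p_same, lambda = lambda,
      sigma_motor = sigma_motor, gamma = gamma),
    class = "context_params"
  )
}

#' Apply the auditory range recalibration gain
#'
#' Multiplies noisy auditory measurements by `rho_a` immediately after their
#' generation; the recalibrated value is what every later inference stage sees,
#' with no correction downstream.
#'
#' @param x_a Noisy auditory measurements (deg).
#' @param rho_a Recalibration gain.
#' @return Recalibrated measurements (deg).
#' @export
#' @examples
#' apply_recalibration(9, 4 / 3)
apply_recalibration <- function(x_a, rho_a) {
  x_a * rho_a
}
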