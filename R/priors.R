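# Prior shape families over stimulus location.
#
# All priors are symmetric about 0, non-increasing in |s|, and normalized by
# trapezoid over the bounded support [-45, 45] on the package's default
# 721-point grid, so every family (closed-form or pivot-based) obeys one
# contract with the numerical engine.

PRIOR_SUPPORT <- c(-RANGE_HALF, RANGE_HALF)
NORMALIZATION_POINTS <- 721

normalization_grid <- function(support = PRIOR_SUPPORT) {
  seq(support[1], support[2], length.out = NORMALIZATION_POINTS)
}

new_prior <- function(family, params, unnorm, support = PRIOR_SUPPORT) {
  grid <- normalization_grid(support)
  z <- trapz(grid, unnorm(grid))
  if (!is.finite(z) || z <= 0) abort("Prior normalization failed (non-positive mass).")
  structure(
    list(family = family, params = params, support = support,
      unnorm = unnorm, norm_const = z),
    class = c(paste0("prior_", tolower(family)), "prior_model")
  )
}

#' Prior families over stimulus location
#'
#' Constructors for the symmetric, centrally peaked priors used by the observer
#' models:
#' * `prior_single_gaussian()`: `p(s) = N(s; 0, sigma_s^2)`.
#' * `prior_two_gaussians()`: `(1 - omega) N(s; 0, sigma_s^2) +
#'   omega N(s; 0, (sigma_s + sigma_delta)^2)`.
#' * `prior_gaussian_laplace()`: `(1 - omega) N(s; 0, sigma_s^2) +
#'   omega Laplace(s; 0, b)`, a narrow-peak/broad-tail mixture.
#'
#' Densities are evaluated with [prior_pdf()] and are normalized over the
#' bounded support `[-45, 45]` degrees.
#'
#' @param sigma_s Gaussian component SD (deg), positive.
#' @param sigma_delta Extra SD of the broad Gaussian component (deg), positive.
#' @param b Laplace scale (deg), positive.
#' @param omega Mixture weight of the broad/Laplace component, in `[0, 1]`.
#' @return A `prior_model` object.
#' @name prior_families
#' @examples
#' pr <- prior_gaussian_laplace(sigma_s = 8, b = 2, omega = 0.5)
#' prior_pdf(pr, c(-10, 0, 10))
NULL

#' @rdname prior_families
#' @export
prior_single_gaussian <- function(sigma_s) {
  stopifnot(sigma_s > 0)
  new_prior("SingleGaussian", list(sigma_s = sigma_s),
    function(s) dnorm(s, 0, sigma_s))
}

#' @rdname prior_families
#' @export
prior_two_gaussians <- function(sigma_s, sigma_delta, omega) {
  stopifnot(sigma_s > 0, sigma_delta > 0)
  assert_scalar_prob(omega, "omega")
  new_prior("TwoGaussians",
    list(sigma_s = sigma_s, sigma_delta = sigma_delta, omega = omega),
    function(s) (1 - omega) * dnorm(s, 0, sigma_s) +
      omega * dnorm(s, 0, sigma_s + sigma_delta))
}

#' @rdname prior_families
#' @export
prior_gaussian_laplace <- function(sigma_s, b, omega) {
  stopifnot(sigma_s > 0, b > 0)
  assert_scalar_prob(omega, "omega")
  new_prior("GaussianLaplace",
    list(sigma_s = sigma_s, b = b, omega = omega),
    function(s) (1 - omega) * dnorm(s, 0, sigma_s) +
      omega / (2 * b) * exp(-abs(s) / b))
}

#' Pivot grid of the semiparametric shapes
#'
#' The 12 fixed stimulus locations at which semiparametric prior and noise
#' shapes carry free values; intermediate values are obtained by monotone cubic
#' interpolation and negative locations by mirror symmetry about 0.
#'
#' @return Numeric vector of pivot locations in degrees.
#' @export
pivot_grid <- function() {
  c(0, 0.1, 0.3, 1, 2, 4, 6, 8, 10, 15, 20, 45)
}

# Lower bound for log-increments: a "flat" shape is representable without -Inf.
LOG_INCREMENT_FLOOR <- log(1e-6)

#' Build a semiparametric (pivot-based) prior
#'
#' The log-density is fixed to 0 at the first pivot and decreases by
#' `exp(theta[j])` at each successive pivot, guaranteeing a density that is
#' monotonically non-increasing in `|s|`. Interpolation between pivots is
#' monotone cubic in log space; the density is then exponentiated, mirrored
#' about 0, and normalized over the support.
#'
#' @param theta 11 finite log-decrement values (one per pivot transition).
#' @param pivots Pivot locations, by default [pivot_grid()].
#' @param support Normalization interval in degrees.
#' @return A `prior_model` object.
#' @export
#' @examples
#' pr <- prior_semiparametric(rep(log(0.2), 11))
#' trapz(seq(-45, 45, length.out = 721), prior_pdf(pr, seq(-45, 45, length.out = 721)))
prior_semiparametric <- function(theta, pivots = pivot_grid(), support = PRIOR_SUPPORT) {
  if (length(theta) != length(pivots) - 1) {
    abort(sprintf("`theta` must have %d values (one per pivot transition).",
      length(pivots) - 1))
  }
  if (any(!is.finite(theta))) abort("`theta` must be finite.")
  log_p <- c(0, -cumsum(exp(pmax(theta, LOG_INCREMENT_FLOOR))))
  interp <- splinefun(pivots, log_p, method = "hyman")
  pr <- new_prior("SemiparametricPivot",
    list(theta = theta, pivots = pivots),
    function(s) exp(interp(pmin(abs(s), max(pivots)))))
  pr$pivot_values <- exp(log_p)
  pr
}

#' Evaluate a prior density
#'
#' @param prior A `prior_model` object.
#' @param s Stimulus locations in degrees.
#' @return Density values (1/deg), normalized over the prior's support.
#' @export
prior_pdf <- function(prior, s) {
  UseMethod("prior_pdf")
}

#' @export
prior_pdf.prior_model <- function(prior, s) {
  prior$unnorm(s) / prior$norm_const
}

#' Apply an exponent to a prior shape
#'
#' Returns the prior with density proportional to `p(s)^gamma`, renormalized
#' over the support. `gamma = 1` leaves the prior unchanged; `gamma = 0` gives
#' a uniform prior over the support. Used by lifted fits to give the frozen
#' semiparametric prior shape a single degree of flexibility.
#'
#' @param prior A `prior_model` object.
#' @param gamma Non-negative exponent.
#' @return A `prior_model` object.
#' @export
apply_prior_exponent <- function(prior, gamma) {
  stopifnot(gamma >= 0)
  if (gamma == 1) return(prior)
  base <- prior
  new_prior(paste0(base$family, "^gamma"),
    c(base$params, list(gamma = gamma)),
    function(s) prior_pdf(base, s)^gamma,
    support = base$support)
}

#' @export
print.prior_model <- function(x, ...) {
  cat("<prior_model>", x$family, "\n")
  scalars <- Filter(function(p) is.numeric(p) && length(p) == 1, x$params)
  if (length(scalars) > 0) {
    cat(" ", paste(names(scalars), signif(unlist(scalars), 4), sep = "=",
      collapse = ", "), "\n")
  }
  invisible(x)
}
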