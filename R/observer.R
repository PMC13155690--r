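# Observer-model container and numerical grid specification.

#' Numerical grids of the likelihood engine
#'
#' All definite integrals are computed by the trapezoidal rule. The stimulus
#' grid spans the full support; measurement grids are centered on the trial's
#' stimulus and span `x_span` noise SDs; bisensory double integrals use
#' `x_points_2d` nodes per dimension. Posterior-mean and causal-posterior
#' fields are tabulated on absolute grids with spacings `shat_spacing` and
#' `field_spacing` and interpolated (linearly / bilinearly) at quadrature
#' nodes. `refine` multiplies every resolution (halving all spacings with
#' `refine = 2`), which is how grid-convergence checks are run.
#'
#' @param s_points Number of stimulus-grid points on the support.
#' @param support Stimulus support in degrees.
#' @param x_points Measurement nodes for 1-D (unisensory) integrals.
#' @param x_span Half-width of measurement grids in noise SDs.
#' @param x_points_2d Measurement nodes per dimension for bisensory integrals.
#' @param shat_spacing Spacing (deg) of the tabulated unisensory posterior-mean
#'   function.
#' @param field_spacing Spacing (deg) of the tabulated bisensory fields
#'   (causal posterior, fused estimate).
#' @param r_points Response-grid points for full response distributions.
#' @param refine Integer resolution multiplier.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(s_points = 721, support = c(-RANGE_HALF, RANGE_HALF),
                      x_points = 201, x_span = 5, x_points_2d = 61,
                      shat_spacing = 0.25, field_spacing = 0.25,
                      r_points = 721, refine = 1) {
  stopifnot(s_points > 2, x_points > 2, x_points_2d > 2, x_span > 0,
    shat_spacing > 0, field_spacing > 0, refine >= 1)
  structure(
    list(
      s_points = as.integer((s_points - 1) * refine + 1),
      support = support,
      x_points = as.integer((x_points - 1) * refine + 1),
      x_span = x_span,
      x_points_2d = as.integer((x_points_2d - 1) * refine + 1),
      shat_spacing = shat_spacing / refine,
      field_spacing = field_spacing / refine,
      r_points = as.integer((r_points - 1) * refine + 1)
    ),
    class = "grid_spec"
  )
}

s_grid_of <- function(grids) {
  seq(grids$support[1], grids$support[2], length.out = grids$s_points)
}

#' Assemble a full Bayesian observer model
#'
#' Bundles a prior over stimulus location, the visual and auditory
#' sensory-noise functions, a causal-inference strategy, the context
#' parameters, and the numerical grids. If `context$gamma != 1`, the prior
#' exponent is applied (and the density renormalized) at construction.
#'
#' @param prior A `prior_model`.
#' @param noise_v,noise_a Visual and auditory `noise_model`s.
#' @param strategy Causal-inference strategy: `"MS"` (model selection), `"MA"`
#'   (model averaging) or `"PM"` (probability matching). Ignored for
#'   unisensory evaluation.
#' @param context A [context_params()] object.
#' @param grids A [grid_spec()].
#' @return An object of class `observer_model`.
#' @export
#' @examples
#' obs <- observer_model(
#'   prior = prior_single_gaussian(10),
#'   noise_v = noise_const(2, "V"), noise_a = noise_const(4, "A"),
#'   strategy = "PM", context = context_params(lambda = 0.02))
observer_model <- function(prior, noise_v, noise_a, strategy = "PM",
                           context = context_params(), grids = grid_spec()) {
  stopifnot(inherits(prior, "prior_model"), inherits(noise_v, "noise_model"),
    inherits(noise_a, "noise_model"), inherits(context, "context_params"),
    inherits(grids, "grid_spec"))
  strategy <- match.arg(strategy, STRATEGIES)
  if (noise_v$modality != "V" || noise_a$modality != "A") {
    abort("`noise_v` must have modality V and `noise_a` modality A.")
  }
  prior_eff <- if (context$gamma != 1) apply_prior_exponent(prior, context$gamma) else prior
  s <- s_grid_of(grids)
  obs <- structure(
    list(prior = prior, prior_eff = prior_eff, noise_v = noise_v,
      noise_a = noise_a, strategy = strategy, context = context, grids = grids,
      s_grid = s,
      prior_w = prior_pdf(prior_eff, s) * trapz_weights(s)),
    class = "observer_model"
  )
  obs
}

#' @export
print.observer_model <- function(x, ...) {
  cat("<observer_model>\n")
  cat("  prior:   ", x$prior$family,
    if (x$context$gamma != 1) sprintf(" (gamma = %g)", x$context$gamma), "\n", sep = "")
  cat("  noise V: ", x$noise_v$family, "; noise A: ", x$noise_a$family, "\n", sep = "")
  cat("  strategy:", x$strategy, "\n")
  ctx <- unlist(x$context)
  cat("  context: ", paste(names(ctx), signif(ctx, 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Effective noise SD on the stimulus grid for a modality / reliability /
# task-context combination.
sigma_on_grid <- function(observer, modality, reliability = NULL, bisensory = FALSE) {
  noise <- if (modality == "V") observer$noise_v else observer$noise_a
  rel <- if (modality == "V") reliability else NULL
  noise_sigma(noise, observer$s_grid, rel, observer$context, bisensory)
}

# Effective noise SD at arbitrary stimulus locations.
sigma_at <- function(observer, modality, s, reliability = NULL, bisensory = FALSE) {
  noise <- if (modality == "V") observer$noise_v else observer$noise_a
  rel <- if (modality == "V") reliability else NULL
  noise_sigma(noise, s, rel, observer$context, bisensory)
}
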