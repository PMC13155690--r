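# Internal numerical helpers: quadrature weights, interpolation, seed streams.

# Trapezoidal weights for a uniformly spaced grid.
trapz_weights <- function(x) {
  n <- length(x)
  h <- (x[n] - x[1]) / (n - 1)
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}

#' Trapezoidal integral
#'
#' Integral of `y` sampled on the (possibly non-uniform) grid `x` by the
#' trapezoidal rule — the quadrature rule used throughout the likelihood
#' engine.
#'
#' @param x Grid (strictly increasing).
#' @param y Function values at `x`.
#' @return The scalar integral.
#' @export
#' @examples
#' trapz(seq(0, pi, length.out = 1001), sin(seq(0, pi, length.out = 1001)))
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Vectorized bilinear interpolation of matrix `f` defined on the uniform grid
# (x0 + (0:(nrow-1)) * hx) x (y0 + (0:(ncol-1)) * hy); queries outside the grid
# are clamped to the boundary.
interp_bilinear <- function(f, x0, hx, y0, hy, xq, yq, clamp = TRUE) {
  nx <- nrow(f)
  ny <- ncol(f)
  u <- (xq - x0) / hx
  v <- (yq - y0) / hy
  if (clamp) {
    u <- pmin.int(pmax.int(u, 0), nx - 1 - 1e-9)
    v <- pmin.int(pmax.int(v, 0), ny - 1 - 1e-9)
  }
  i <- floor(u)
  j <- floor(v)
  fu <- u - i
  fv <- v - j
  idx <- i + j * nx + 1 # linear index of (i+1, j+1) in column-major f
  f[idx] * (1 - fu) * (1 - fv) +
    f[idx + 1] * fu * (1 - fv) +
    f[idx + nx] * (1 - fu) * fv +
    f[idx + nx + 1] * fu * fv
}

# Fast linear interpolation with boundary clamping (uniform grid).
interp_linear <- function(xgrid, y, xq) {
  x0 <- xgrid[1]
  h <- xgrid[2] - xgrid[1]
  n <- length(xgrid)
  u <- pmin.int(pmax.int((xq - x0) / h, 0), n - 1 - 1e-9)
  i <- floor(u)
  fu <- u - i
  y[i + 1] * (1 - fu) + y[i + 2] * fu
}

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic step in the package (participant simulation, optimizer
#' restarts, bootstrap resampling) draws its seed from a master seed through
#' this function, so partial reruns of a pipeline reproduce exactly.
#'
#' @param seed Master seed (integer).
#' @param ... Additional labels (participant ids, restart indices, strings)
#'   identifying the substream.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "participant", 3)
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Floor densities before log so the objective stays finite under pathological
# parameters.
DENSITY_FLOOR <- 1e-300

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
}
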