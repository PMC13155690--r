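---
title: "Bayesian causal-inference observer models for audiovisual localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian causal-inference observer models for audiovisual localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalobs)
```

## The modeling problem

`causalobs` implements a family of Bayesian observer models for an
audiovisual spatial task battery with five trial types: unisensory visual
(UV) and auditory (UA) localization, a bisensory causal judgment (BC, "same
source or different sources?"), and bisensory localization of either the
visual (BV) or auditory (BA) stimulus. The observer receives noisy
measurements

$$x_V \sim \mathcal N(s_V,\ \sigma_V^2(s_V)), \qquad
  x_A \sim \mathcal N(s_A,\ \sigma_A^2(s_A)),$$

with *eccentricity-dependent* (heteroskedastic) noise functions
$\sigma(s)$, holds a symmetric, centrally peaked prior $p(s)$ over stimulus
location shared across modalities, and inverts the generative model by
Bayes' rule. Unisensory location reports are posterior means corrupted by
Gaussian motor noise (SD $\sigma_{motor}$) with a uniform lapse (rate
$\lambda$) over the response range $[-45^\circ, 45^\circ]$. Bisensory
behavior adds causal inference: the observer computes the posterior
probability that the two cues share a source,

$$p(C{=}1 \mid x_V, x_A) =
  \frac{p_{same}\, L_1}{p_{same}\, L_1 + (1-p_{same})\, L_2},$$

where $L_1 = \int p(x_V|s)\,p(x_A|s)\,p(s)\,ds$ and $L_2$ is the product of
the single-cue evidences, then maps the per-hypothesis posterior-mean
estimates $\hat s_{C=1}$ (fused) and $\hat s_{C=2}$ (single cue) to a
response by one of three strategies:

* **MS** (model selection): report the estimate of the more probable
  hypothesis;
* **MA** (model averaging): report the posterior-weighted combination;
* **PM** (probability matching): sample the hypothesis with probability
  equal to its posterior.

Three further context mechanisms are modeled. Visual reliability scalings
$\alpha_{med}, \alpha_{low}$ multiply $\sigma_V(s)$ on medium-/low-
reliability trials. Unisensory-to-bisensory scalings $\beta_V, \beta_A$
multiply the noise functions on bisensory trials, accommodating the
possibility that noise is higher when attention is split across modalities.
An auditory range recalibration gain $\rho_A$ multiplies the noisy auditory
measurement immediately after its generation — the observer "stretches" the
narrower auditory stimulus range ($\pm 15^\circ$) toward the wider visual
range ($\pm 20^\circ$); $\rho_A = 4/3$ corresponds to a full remapping and
$\rho_A = 1$ to none. The recalibrated value is what every later inference
stage sees; it is never corrected downstream.

## Shape families

Priors: a single zero-mean Gaussian (`SingleGaussian`, $\sigma_s$); a
two-Gaussian mixture (`TwoGaussians`, $\sigma_s, \sigma_\Delta, \omega$); a
Gaussian–Laplace mixture (`GaussianLaplace`, $\sigma_s, b, \omega$), whose
narrow Laplace peak plus broad Gaussian tail is the shape that best
describes human data in this paradigm. Noise: constant (`Const`,
$\sigma_0$) or saturating exponential (`Exp`),
$\sigma(s) = \sigma_0 + k_1 (1 - e^{-k_2 |s|})$, which dips at straight
ahead and plateaus at $\sigma_0 + k_1$ in the periphery.

Semiparametric shapes free the functional form: values at 12 pivot
locations $\{0, 0.1, 0.3, 1, 2, 4, 6, 8, 10, 15, 20, 45\}^\circ$ are free
parameters, encoded as a base value plus log-increments so that noise
shapes are positive and non-decreasing in $|s|$ and (log-)priors are
non-increasing, with mirror symmetry about $0$. Between pivots we
interpolate with a *monotone* cubic (Hyman-filtered) spline. Plain cubic
interpolation can overshoot between knots and transiently violate the
monotonicity that the construction is supposed to guarantee; the monotone
interpolant enforces the stated constraint exactly, at the cost of a
possibly microscopic difference from an unconstrained cubic. Log-increments
are bounded below at $\log 10^{-6}$ so flat shapes are representable
without infinities.

All priors — parametric and semiparametric — are normalized by trapezoid
over the bounded support $[-45^\circ, 45^\circ]$ on a fixed 721-point grid.
The response range is the only "full range" in the design, and normalizing
every family on one grid keeps all priors on the same contract as the
numerical engine (truncation mass is negligible at fitted scales). A prior
exponent $\gamma$ (density $\propto p(s)^\gamma$, renormalized) gives
lifted fits one degree of shape flexibility.

## Numerics

All definite integrals use the trapezoidal rule. Defaults
(`grid_spec()`): a 721-point stimulus grid on $[-45^\circ, 45^\circ]$
(0.25°); measurement integrals over stimulus $\pm 5$ noise SDs with 201
nodes (unisensory) or $61 \times 61$ nodes (bisensory double integrals).
Two quantities are tabulated on absolute grids (nodes at integer multiples
of the spacing) and interpolated at quadrature nodes: the unisensory
posterior-mean function $\hat s(x)$ (linear interpolation, 0.25° spacing,
adaptively coarsened to a sixth of the central noise SD when the likelihood
is wide, spanning the measurement nodes out to four noise SDs with edge
clamping beyond) and the bisensory fields $p(C{=}1|x_V, m_A)$ and
$\hat s_{C=1}(x_V, m_A)$ (bilinear, 0.25° spacing or a tenth of the
combined central noise SD, whichever is finer than 0.05°). Absolute grids
make cached group-level tables bit-identical to per-trial rebuilds, which
is how the caching logic is tested. Internal measurements are capped at
$\pm 180^\circ$, far outside the support, where estimates saturate.

Two integrands are discontinuous: the MS/MA causal judgment integrates the
indicator $p(C{=}1|\cdot) \ge 0.5$ (ties count as $C = 1$, a measure-zero
convention fixed for determinism). Naive quadrature of the indicator
oscillates with grid alignment, so the engine locates the decision boundary
along the visual-measurement axis by root interpolation on the field grid
and accumulates the exact Gaussian measurement mass of each super-threshold
interval with `pnorm`; only the (smooth) auditory direction is left to
quadrature. The analogous jump in MS localization densities is integrated with doubled
measurement-node density for that strategy; its grid error at defaults is a
few $10^{-4}$ in density.
Halving every spacing (`grid_spec(refine = 2)`) changes reported
probabilities by under $10^{-3}$, and the engine agrees with independently
derived conjugate-Gaussian closed forms to better than $10^{-3}$ for the
constant-noise, Gaussian-prior observer. The motor-noise Gaussian is not
truncated at the response range (out-of-range data responses are handled by
the load-time discard rule instead), and per-trial densities are floored at
$10^{-300}$ before the log so the objective stays finite under pathological
parameters.

## Simulator as an independent path

`simulate_responses()` never touches the engine's tabulated fields: it
draws measurements per trial, applies $\rho_A$, computes posterior means by
direct quadrature at the sampled measurement, samples the PM hypothesis
explicitly, and adds motor noise and lapses. Simulator and engine therefore
serve as mutual oracles; their agreement is checked by chi-square
goodness-of-fit of $10^5$ simulated responses per task and strategy against
binned engine densities.

The synthetic-data generator reproduces the experiment design: 15
participants; per participant 500 UV, 500 UA, 1000 bisensory-localization
(BV/BA assigned with equal probability) and 1000 BC trials; auditory
locations uniform on the seven speakers $\{0, \pm5, \pm10, \pm15\}^\circ$;
visual locations uniform on $[-20, 20]^\circ$ except common-source
bisensory trials ($p = 0.5$), which inherit the speaker location; three
equiprobable visual reliability levels. Synthetic participants draw their
parameters uniformly from the ranges in
`inst/extdata/synthetic_params.json` — the package's own choice of
realistic degree-scale values for this paradigm (e.g. central visual noise
under a degree rising to a few degrees peripherally, auditory noise of a
few degrees, recalibration gains near $4/3$, bisensory noise inflation
$\beta_A > \beta_V > 1$), documented here once and not tuned thereafter.
What passing simulator-based tests shows is internal consistency and
identifiability under the stated design — not that human data obey these
shapes; the generator has no trial-order effects, no learning, and
perfectly Gaussian measurement noise.

The unisensory likelihood's hot loops (the tabulated posterior mean and the
per-trial response density) are implemented in C++ (Rcpp), and group-level
density vectors are cached content-addressed — the cache key hashes every
numerical input, so hits are exact; this makes finite-difference gradients,
which perturb one parameter at a time, several-fold cheaper.

## Fitting

`negative_log_likelihood()` is the summed per-trial negative log
probability/density (categorical for BC, continuous otherwise).
`fit_mle()` maximizes it over a scaled-logit transform of every bounded
parameter onto the real line. Bounds are generous physical envelopes:
$\sigma_0, \sigma_{motor} \in [0.05, 30]$°, $k_1 \in [0, 40]$°,
$k_2 \in [10^{-3}, 5]$ 1/°, prior scales in $[0.25, 60]$°, probabilities in
$[10^{-4}, 1 - 10^{-4}]$, multipliers in $[0.2, 10]$, $\rho_A \in [0.5, 2]$,
$\gamma \in [0, 5]$.

Initializations are randomized uniformly within reasonable ranges (the
same plausible ranges used by the generator) by Latin-hypercube sampling;
semiparametric fits add flat-shape starts — all three functions flat, with
noise levels on a small grid $\{1, 2, 4, 8\}^\circ$ per modality. Restarts
run in two phases: a cheap exploration pass from every start and a deep
polish of the best solution; the returned optimum is the best point seen
anywhere, so a warm start can never be degraded. The optimizer is a
pluggable contract; the default for up to 20 free parameters is L-BFGS-B on
the unconstrained transformed space with finite-difference gradients —
appropriate because the objective is smooth and deterministic given fixed
grids — with Nelder-Mead available as a derivative-free alternative and a
compact CMA-ES (written in-package) as the default above 20 parameters,
where quasi-Newton exploration of the 40-parameter semiparametric landscape
is less reliable.

Lifted fits (`lift_semiparametric()`) freeze the 24 + 11 semiparametric
shape values estimated from unisensory data and refit exactly nine context
parameters ($\alpha_{med}, \alpha_{low}, \lambda, \sigma_{motor}, \rho_A,
p_{same}, \beta_V, \beta_A, \gamma$) on all five tasks.
`lifted_complexity()` scores them either by the nine free parameters or
with the 35 frozen shapes added back, making the double-dipping of shapes
already fitted on unisensory data visible in AIC/BIC.

Model comparison uses $\mathrm{AIC} = 2\,\mathrm{NLL} + 2k$ and
$\mathrm{BIC} = 2\,\mathrm{NLL} + k \ln N$ with $N$ the per-participant
trial count of the fitted task scope (roughly 1000 unisensory, 3000
all-task) — the per-participant convention is a package decision where the
formula leaves $N$ unqualified. Group error bars are bootstrap 95%
intervals over participants (default $10^4$ resamples, seeded), matching
group-level inference over a participant sample.

## Recovery harnesses and problem sizes

`run_model_recovery()` simulates a group from each candidate, refits every
candidate to every simulated participant, and differences group-summed
NLL/AIC/BIC against the generating model; `run_parameter_recovery()` pairs
generating and refitted parameters and summarizes Spearman rank
correlations and median absolute relative errors across participants.

The harnesses default to a reduced tier chosen for routine runs: 5
simulated participants, a unisensory candidate subset
(`Const-SingleGaussian_1`, `Const-GaussianLaplace`, `Exp-SingleGaussian`,
`Exp-GaussianLaplace`), a few hundred trials per participant, one to three
restarts, and coarser quadrature (`recovery_grids()`: 241-point stimulus
grid, 61 measurement nodes, 0.5° tables), which biases the likelihood by
well under one NLL unit per thousand trials relative to full resolution.
The full-scale analysis — 15 participants, the complete candidate set,
full grids and restart budgets — is the same code with larger arguments and
is the package's long-running mode. Parameters known to be weakly
identified at these scales ($k_2$, the mixture weight $\omega$, the Laplace
scale $b$, $\gamma$) are reported but excluded from pass/fail thresholds;
a genuine partial trade-off also links $\sigma_{0V}$ and $\sigma_{motor}$
at the response center, which is why central-noise recovery is judged by
rank agreement rather than absolute error.

## Known limitations

* Strategies beyond MS/MA/PM (heuristic or rule-based causal decisions) are
  out of scope, as are posterior-median or MAP readouts, asymmetric or
  non-monotone shapes, and circular (wrapped) geometry — the design's
  narrow ranges justify working on the line.
* Very narrow shape components (Laplace scale or Gaussian SD below the
  default 0.25° grid spacing) are under-resolved; bounds keep fits above
  that scale, but user-supplied shapes near the lower bounds warrant a
  `refine = 2` check.
* Whether the original analyses truncated the motor Gaussian at the
  response range, or let $\rho_A$ also rescale the auditory noise
  magnitude, is not documented; this implementation records one choice for
  each (untruncated; pure measurement gain) so residual discrepancies are
  attributable.
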