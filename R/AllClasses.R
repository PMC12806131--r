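#' @import methods
#' @importFrom stats rnorm rpois runif rexp dnorm dpois pnorm ppois pgamma
#'   lm coef integrate setNames ecdf ks.test
#' @importFrom graphics hist
NULL

## ---------------------------------------------------------------------------
## Waiting-time laws
## ---------------------------------------------------------------------------

#' Virtual parent of the inter-division waiting-time laws
#'
#' The cell-cycle duration between successive divisions is modelled by one of
#' three laws: a heavy-tailed power law with tail exponent in (0,1) (no mean;
#' subdiffusive renewal counting), a Pareto law with exponent in (1,2) (finite
#' mean, infinite variance), or an exponentially tempered one-sided stable law
#' (anomalous at short times, normal beyond the tempering horizon).
#'
#' @seealso [powerLawWait()], [paretoWait()], [temperedWait()]
#' @export
setClass("WaitingTimeModel", representation("VIRTUAL"))

#' @describeIn WaitingTimeModel Pareto law with shape `alpha` in (0,1) and
#'   scale `t0`; the default scale `t0 = Gamma(1-alpha)^(-1/alpha)` normalises
#'   the small-s Laplace transform to `1 - s^alpha`.
#' @export
setClass("PowerLawWait", contains = "WaitingTimeModel",
  representation(alpha = "numeric", t0 = "numeric"))

setValidity("PowerLawWait", function(object) {
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0 || object@alpha >= 1)
    return("'alpha' must be a single value in (0, 1)")
  if (length(object@t0) != 1L || !is.finite(object@t0) || object@t0 <= 0)
    return("'t0' must be a single positive value")
  TRUE
})

#' @describeIn WaitingTimeModel Pareto law with shape `alpha` in (1,2) and
#'   scale `tau0`. Mean waiting time `T = alpha*tau0/(alpha-1)`; fractional
#'   coefficient `C = |Gamma(1-alpha)| * tau0^alpha`.
#' @export
setClass("ParetoWait", contains = "WaitingTimeModel",
  representation(alpha = "numeric", tau0 = "numeric"))

setValidity("ParetoWait", function(object) {
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 1 || object@alpha >= 2)
    return("'alpha' must be a single value in (1, 2)")
  if (length(object@tau0) != 1L || !is.finite(object@tau0) || object@tau0 <= 0)
    return("'tau0' must be a single positive value")
  TRUE
})

#' @describeIn WaitingTimeModel Tempered one-sided stable law with stability
#'   index `gamma` in (0,1), scale `B` and tempering rate `xi >= 0`; Laplace
#'   transform `exp(-B^gamma*(s+xi)^gamma + B^gamma*xi^gamma)`.
#' @export
setClass("TemperedWait", contains = "WaitingTimeModel",
  representation(gamma = "numeric", B = "numeric", xi = "numeric"))

setValidity("TemperedWait", function(object) {
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma <= 0 || object@gamma >= 1)
    return("'gamma' must be a single value in (0, 1)")
  if (length(object@B) != 1L || !is.finite(object@B) || object@B <= 0)
    return("'B' must be a single positive value")
  if (length(object@xi) != 1L || !is.finite(object@xi) || object@xi < 0)
    return("'xi' must be a single nonnegative value")
  TRUE
})

## ---------------------------------------------------------------------------
## Jump (per-division shortening) laws
## ---------------------------------------------------------------------------

#' Per-division telomere shortening-length law
#'
#' The base pairs lost in one division are `L = L1 + L2` with
#' `L1 ~ Normal(mu, sigma^2)` (incomplete end replication) and
#' `L2 ~ Poisson(lambda)` (exonuclease digestion), independent.
#' Mean `lambda + mu`, variance `sigma^2 + lambda`.
#'
#' @export
setClass("JumpModel",
  representation(lambda = "numeric", mu = "numeric", sigma = "numeric"))

setValidity("JumpModel", function(object) {
  for (s in c("lambda", "mu", "sigma")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) return(sprintf("'%s' must be a single finite value", s))
  }
  if (object@lambda <= 0) return("'lambda' must be positive")
  if (object@sigma <= 0) return("'sigma' must be positive")
  TRUE
})

#' Three-mechanism shortening decomposition
#'
#' Weighted combination of incomplete end replication (Normal `L1`),
#' exonuclease digestion (Poisson `L2`, probability `pExo`) and oxidative
#' damage (Normal `L3` per damaged base, probability `pOx`, `nDamaged` bases):
#' `L = (1/4) L1 + pExo (1/4) L2 + pOx (1/2) L3 N`.
#'
#' @export
setClass("ThreeMechanismModel",
  representation(mu1 = "numeric", sigma1 = "numeric", lambda2 = "numeric",
                 mu3 = "numeric", sigma3 = "numeric", nDamaged = "numeric",
                 pExo = "numeric", pOx = "numeric"))

setValidity("ThreeMechanismModel", function(object) {
  if (object@pExo < 0 || object@pExo > 1) return("'pExo' must lie in [0, 1]")
  if (object@pOx < 0 || object@pOx > 1) return("'pOx' must lie in [0, 1]")
  if (object@sigma1 < 0 || object@sigma3 < 0) return("standard deviations must be nonnegative")
  if (object@lambda2 < 0) return("'lambda2' must be nonnegative")
  if (object@nDamaged < 0) return("'nDamaged' must be nonnegative")
  TRUE
})

## ---------------------------------------------------------------------------
## Telomere geometry and paths
## ---------------------------------------------------------------------------

#' Initial and critical telomere lengths
#'
#' A cell senesces once the cumulative shortening reaches `l0 - lc`
#' (initial minus critical length); that difference is the absorbing
#' threshold for the shortening process.
#'
#' @export
setClass("TelomereConfig", representation(l0 = "numeric", lc = "numeric"))

setValidity("TelomereConfig", function(object) {
  if (!is.finite(object@l0) || !is.finite(object@lc)) return("lengths must be finite")
  if (object@lc < 0) return("'lc' must be nonnegative")
  if (object@l0 <= object@lc) return("'l0' must exceed 'lc' (positive threshold)")
  TRUE
})

#' A single renewal trajectory of cumulative shortening
#'
#' Right-continuous step function: `epochs` are the division times, `lengths`
#' the cumulative base pairs lost just after each division, `L(0) = 0`.
#' If `absorbed`, the trajectory stopped at `absorptionTime` when the
#' cumulative shortening first reached the threshold (the final jump may
#' overshoot it: leapover).
#'
#' @export
setClass("Trajectory",
  representation(epochs = "numeric", lengths = "numeric", absorbed = "logical",
                 absorptionTime = "numeric", horizon = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@epochs) != length(object@lengths))
    return("'epochs' and 'lengths' must have equal length")
  if (length(object@epochs) && any(diff(object@epochs) <= 0))
    return("'epochs' must be strictly increasing")
  if (length(object@epochs) && object@epochs[1L] <= 0)
    return("'epochs' must be positive")
  if (length(object@horizon) != 1L || object@horizon <= 0)
    return("'horizon' must be a single positive value")
  if (object@absorbed && is.na(object@absorptionTime))
    return("absorbed trajectories need an 'absorptionTime'")
  TRUE
})

#' An ensemble of independent shortening trajectories
#'
#' Compact columnar storage (lists of epoch/length vectors) for large
#' ensembles; individual [Trajectory] objects are materialised on demand via
#' [trajectory()].
#'
#' @export
setClass("Ensemble",
  representation(epochs = "list", lengths = "list", absorbed = "logical",
                 absorptionTime = "numeric", horizon = "numeric",
                 jump = "JumpModel", wait = "WaitingTimeModel",
                 telomere = "TelomereConfig", seed = "integer"))

setValidity("Ensemble", function(object) {
  n <- length(object@epochs)
  if (length(object@lengths) != n || length(object@absorbed) != n ||
      length(object@absorptionTime) != n)
    return("trajectory columns must have equal length")
  TRUE
})

#' Ensemble shortening lengths on a fixed time grid
#'
#' Matrix representation (trajectories in rows, grid times in columns) of the
#' cumulative shortening without absorption, used for moment estimation.
#' Jump sums between grid times are drawn in closed form (Normal + Poisson
#' sums are again Normal + Poisson), which is exact for the finite-dimensional
#' law on the grid.
#'
#' @export
setClass("LengthGrid",
  representation(times = "numeric", L = "matrix", jump = "JumpModel",
                 wait = "WaitingTimeModel", seed = "integer"))

setValidity("LengthGrid", function(object) {
  if (ncol(object@L) != length(object@times))
    return("'L' must have one column per grid time")
  if (any(diff(object@times) <= 0)) return("'times' must be strictly increasing")
  if (any(object@times <= 0)) return("'times' must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## Analytics containers
## ---------------------------------------------------------------------------

#' A moment of the shortening process on a time grid
#'
#' Holds mean, second moment or ensemble-averaged mean squared displacement
#' (EAMSD) values, either closed-form ("analytic"/"asymptotic") or estimated
#' from an ensemble ("empirical"), with an optional fitted log-log slope.
#'
#' @export
setClass("MomentCurve",
  representation(times = "numeric", values = "numeric", kind = "character",
                 source = "character", fit = "list"))

setValidity("MomentCurve", function(object) {
  if (length(object@times) != length(object@values))
    return("'times' and 'values' must have equal length")
  if (any(object@times <= 0) || any(diff(object@times) <= 0))
    return("'times' must be positive increasing")
  if (!object@kind %in% c("mean", "second", "eamsd"))
    return("'kind' must be 'mean', 'second' or 'eamsd'")
  if (object@kind == "eamsd" && any(object@values < -1e-9))
    return("EAMSD values must be nonnegative")
  TRUE
})

#' Diffusion-regime classification of a waiting-time law
#'
#' Predicted EAMSD power-law exponent and regime label; for the finite-mean
#' Pareto family the competition ratio `C/T` is reported alongside the label.
#'
#' @export
setClass("RegimeLabel",
  representation(regime = "character", exponent = "numeric",
                 ctRatio = "numeric"))

setValidity("RegimeLabel", function(object) {
  if (!object@regime %in% c("subdiffusive", "superdiffusive", "normal", "mixed"))
    return("unknown regime label")
  TRUE
})

#' Gridded solution of a shortening-length Fokker-Planck equation
#'
#' Density snapshots `p(L, t)` on cell centres `L` at the requested snapshot
#' times, together with the surviving (not yet absorbed) probability mass at
#' every time step.
#'
#' @export
setClass("FPESolution",
  representation(L = "numeric", times = "numeric", p = "matrix",
                 survivalTimes = "numeric", survival = "numeric",
                 regime = "character", dt = "numeric"))

setValidity("FPESolution", function(object) {
  if (nrow(object@p) != length(object@L)) return("'p' must have one row per L node")
  if (ncol(object@p) != length(object@times)) return("'p' must have one column per snapshot time")
  if (length(object@p) && min(object@p) < -1e-6 * max(abs(object@p), 1e-300))
    return("density must be nonnegative up to scheme tolerance")
  TRUE
})

#' Backward Feynman-Kac solution for an occupation-type functional
#'
#' Values of `G_{L0}(p, t)`, the Laplace (or Fourier) transform in the
#' functional variable of the distribution of `A = integral of U(L(tau))`,
#' on a grid of transform values `p` and times `t`, read off at starting
#' point `L0`.
#'
#' @export
setClass("FKSolution",
  representation(p = "numeric", times = "numeric", G = "matrix",
                 L0 = "numeric", mode = "character", threshold = "numeric"))

setValidity("FKSolution", function(object) {
  if (nrow(object@G) != length(object@p)) return("'G' must have one row per p value")
  if (ncol(object@G) != length(object@times)) return("'G' must have one column per time")
  if (!object@mode %in% c("laplace", "fourier")) return("mode must be 'laplace' or 'fourier'")
  TRUE
})

#' Estimated density of a path functional
#'
#' Histogram or kernel estimate of the occupation-time or first-passage-time
#' density, with the censored-at-horizon probability mass reported separately
#' (never silently dropped).
#'
#' @export
setClass("FunctionalDensity",
  representation(mids = "numeric", density = "numeric", breaks = "numeric",
                 censoredFraction = "numeric", atom = "numeric",
                 atomMass = "numeric", estimator = "character",
                 bandwidth = "numeric", n = "integer"))

setValidity("FunctionalDensity", function(object) {
  if (any(object@density < 0)) return("density must be nonnegative")
  if (object@censoredFraction < 0 || object@censoredFraction > 1)
    return("'censoredFraction' must lie in [0, 1]")
  TRUE
})

#' A complete, serialisable run configuration
#'
#' Bundles the jump law, waiting-time law, telomere geometry, ensemble size,
#' horizon and seed; round-trips losslessly through JSON via
#' [writeRunConfig()] / [readRunConfig()].
#'
#' @export
setClass("RunConfig",
  representation(jump = "JumpModel", wait = "WaitingTimeModel",
                 telomere = "TelomereConfig", nTraj = "integer",
                 horizon = "numeric", seed = "integer", label = "character"))

setValidity("RunConfig", function(object) {
  if (object@nTraj < 1L) return("'nTraj' must be at least 1")
  if (object@horizon <= 0) return("'horizon' must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## show() methods
## ---------------------------------------------------------------------------

setMethod("show", "PowerLawWait", function(object) {
  cat(sprintf("PowerLawWait: alpha = %g, t0 = %g (heavy tail, no mean)\n",
              object@alpha, object@t0))
})

setMethod("show", "ParetoWait", function(object) {
  Tm <- object@alpha * object@tau0 / (object@alpha - 1)
  cat(sprintf("ParetoWait: alpha = %g, tau0 = %g (mean wait T = %g)\n",
              object@alpha, object@tau0, Tm))
})

setMethod("show", "TemperedWait", function(object) {
  cat(sprintf("TemperedWait: gamma = %g, B = %g, xi = %g (crossover ~ %g)\n",
              object@gamma, object@B, object@xi,
              if (object@xi > 0) 1 / object@xi else Inf))
})

setMethod("show", "JumpModel", function(object) {
  cat(sprintf(
    "JumpModel: Normal(mu = %g, sd = %g) + Poisson(lambda = %g) bp/division\n  mean = %g bp, variance = %g bp^2\n",
    object@mu, object@sigma, object@lambda,
    object@lambda + object@mu, object@sigma^2 + object@lambda))
})

setMethod("show", "TelomereConfig", function(object) {
  cat(sprintf("TelomereConfig: l0 = %g bp, lc = %g bp (threshold %g bp)\n",
              object@l0, object@lc, object@l0 - object@lc))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d divisions over [0, %g]%s\n",
              length(object@epochs), object@horizon,
              if (object@absorbed)
                sprintf(", absorbed at t = %g", object@absorptionTime)
              else ", not absorbed"))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d trajectories, horizon %g, %.1f%% absorbed (seed %d)\n",
              length(object@epochs), object@horizon,
              100 * mean(object@absorbed), object@seed))
})

setMethod("show", "LengthGrid", function(object) {
  cat(sprintf("LengthGrid: %d trajectories on %d grid times in [%g, %g]\n",
              nrow(object@L), length(object@times),
              object@times[1L], object@times[length(object@times)]))
})

setMethod("show", "MomentCurve", function(object) {
  cat(sprintf("MomentCurve (%s, %s): %d times in [%g, %g]",
              object@kind, object@source, length(object@times),
              object@times[1L], object@times[length(object@times)]))
  if (length(object@fit))
    cat(sprintf("; fitted log-log slope %.3f", object@fit$slope))
  cat("\n")
})

setMethod("show", "RegimeLabel", function(object) {
  cat(sprintf("RegimeLabel: %s, predicted EAMSD exponent %g", object@regime,
              object@exponent))
  if (!is.na(object@ctRatio)) cat(sprintf(" (C/T = %.3g)", object@ctRatio))
  cat("\n")
})

setMethod("show", "FPESolution", function(object) {
  cat(sprintf("FPESolution (regime %s): %d L nodes, %d snapshots, final survival %.4f\n",
              object@regime, length(object@L), length(object@times),
              object@survival[length(object@survival)]))
})

setMethod("show", "FKSolution", function(object) {
  cat(sprintf("FKSolution (%s mode): %d p values x %d times, L0 = %g, threshold = %g\n",
              object@mode, length(object@p), length(object@times), object@L0,
              object@threshold))
})

setMethod("show", "FunctionalDensity", function(object) {
  cat(sprintf("FunctionalDensity (%s): %d bins, censored fraction %.3f\n",
              object@estimator, length(object@mids), object@censoredFraction))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig '%s': n = %d, horizon = %g, seed = %d\n",
              object@label, object@nTraj, object@horizon, object@seed))
  show(object@wait); show(object@jump); show(object@telomere)
})
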