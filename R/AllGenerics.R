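#' Draw waiting times
#'
#' Samples `n` i.i.d. inter-division waiting times from a waiting-time law.
#' All draws are positive; Pareto-type draws never fall below the scale
#' parameter. Reproducible under [set.seed()] (or the `seed` argument).
#'
#' @param model a [WaitingTimeModel-class] object
#' @param n number of draws (positive integer)
#' @param seed optional integer seed applied before sampling
#' @return numeric vector of `n` positive waiting times
#' @export
setGeneric("sampleWait", function(model, n, seed = NULL) standardGeneric("sampleWait"))

#' Waiting-time probability density
#'
#' @param model a [WaitingTimeModel-class] object
#' @param t positive times (vectorised)
#' @param ... method-specific options
#' @return density values (nonnegative)
#' @export
setGeneric("waitPDF", function(model, t, ...) standardGeneric("waitPDF"))

#' Waiting-time Laplace transform
#'
#' Exact Laplace transform `E[exp(-s * tau)]` of the waiting-time law:
#' equals 1 at `s = 0` and decreases monotonically in `s`.
#'
#' @param model a [WaitingTimeModel-class] object
#' @param s nonnegative transform values (vectorised)
#' @return transform values in (0, 1]
#' @export
setGeneric("waitLaplace", function(model, s) standardGeneric("waitLaplace"))

#' Waiting-time survival function
#'
#' `W(t) = P(tau > t)`, the probability that no division (hence no change in
#' the shortening length) has occurred by time `t`.
#'
#' @param model a [WaitingTimeModel-class] object
#' @param t nonnegative times (vectorised)
#' @return probabilities in [0, 1], nonincreasing in `t`
#' @export
setGeneric("waitSurvival", function(model, t) standardGeneric("waitSurvival"))

#' Mean waiting time
#'
#' Finite for `ParetoWait` (`alpha*tau0/(alpha-1)`) and `TemperedWait` with
#' `xi > 0` (`gamma*B^gamma*xi^(gamma-1)`); infinite for `PowerLawWait`.
#'
#' @param model a [WaitingTimeModel-class] object
#' @return the mean (possibly `Inf`)
#' @export
setGeneric("waitMean", function(model) standardGeneric("waitMean"))

#' Empirical ensemble-averaged mean squared displacement
#'
#' Computes `<L^2(t)> - <L(t)>^2` across trajectories at each grid time.
#'
#' @param x a [LengthGrid-class] or [Ensemble-class] (simulated without
#'   absorption)
#' @param times evaluation grid (defaults to the grid stored in `x`)
#' @return a [MomentCurve-class] of kind `"eamsd"`, source `"empirical"`
#' @export
setGeneric("eamsdEmpirical", function(x, times = NULL) standardGeneric("eamsdEmpirical"))

#' Empirical ensemble mean
#'
#' @inheritParams eamsdEmpirical
#' @return a [MomentCurve-class] of kind `"mean"`, source `"empirical"`
#' @export
setGeneric("meanEmpirical", function(x, times = NULL) standardGeneric("meanEmpirical"))

#' Classify the diffusion regime of the shortening process
#'
#' Predicts the EAMSD power-law exponent implied by the waiting-time law:
#' `2*alpha` for the infinite-mean power law (subdiffusive below
#' `alpha = 0.5`, superdiffusive above), and for the finite-mean Pareto
#' family a label selected by the competition ratio `C/T` between the
#' fractional coefficient `C = |Gamma(1-alpha)|*tau0^alpha` and the mean wait
#' `T`: ratio below `cutoffs[1]` gives normal diffusion (exponent 1), above
#' `cutoffs[2]` the transient exponent `4 - 2*alpha`, otherwise the mixed
#' regime with dominant long-time exponent `3 - alpha`. The raw ratio is
#' always reported so users are not bound by the cutoff labels. Tempered
#' laws are classified by comparing the observation horizon with the
#' tempering time `1/xi` (documented heuristic).
#'
#' @param model a [WaitingTimeModel-class] object
#' @param cutoffs length-2 cutoffs on `C/T` for the Pareto family
#' @param horizon observation horizon (used for tempered laws only)
#' @return a [RegimeLabel-class]
#' @export
setGeneric("classifyRegime",
  function(model, cutoffs = c(0.1, 10), horizon = NULL) standardGeneric("classifyRegime"))
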