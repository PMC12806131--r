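## Closed-form and empirical moments of the shortening process; EAMSD
## slope fitting and diffusion-regime classification.

## jump-variance convention: the macroscopic equations carry sigma^2 as the
## diffusion coefficient; the exact Normal+Poisson jump variance is
## sigma^2 + lambda. Both are supported everywhere a variance enters.
jumpVar <- function(jump, convention = c("macroscopic", "exact")) {
  convention <- match.arg(convention)
  if (convention == "macroscopic") jump@sigma^2 else jump@sigma^2 + jump@lambda
}

#' Closed-form ensemble mean of the shortening length
#'
#' For the infinite-mean waiting law (`alpha` in (0,1)):
#' `<L(t)> = (lambda+mu) t^alpha / (K Gamma(1+alpha))` with
#' `K = Gamma(1-alpha) t0^alpha` (equal to 1 at the default scale). For the
#' finite-mean Pareto family the full two-term expression
#' `(lambda+mu) (t/T + C t^(2-alpha) / (T^2 Gamma(3-alpha)))` is used by
#' default; the `"normal"` and `"fractional"` limit branches are available
#' on request.
#'
#' @param wait a [WaitingTimeModel-class] (power-law families)
#' @param jump a [JumpModel-class]
#' @param t positive times (vectorised)
#' @param branch for `ParetoWait`: `"full"` (default), `"normal"`
#'   (`C/T << 1` limit) or `"fractional"` (`C/T >> 1` limit)
#' @return mean shortening lengths (bp)
#' @export
meanAnalytic <- function(wait, jump, t, branch = c("full", "normal", "fractional")) {
  branch <- match.arg(branch)
  stopifnot(all(t > 0))
  lm <- jumpMean(jump)
  if (is(wait, "PowerLawWait")) {
    K <- lowTailCoefficient(wait)
    return(lm * t^wait@alpha / (K * gamma(1 + wait@alpha)))
  }
  if (!is(wait, "ParetoWait"))
    stop("closed-form moments are available for the power-law families only")
  ct <- ctCoefficients(wait)
  a <- wait@alpha
  frac <- ct[["C"]] * t^(2 - a) / (ct[["T"]]^2 * gamma(3 - a))
  switch(branch,
         full = lm * (t / ct[["T"]] + frac),
         normal = lm * t / ct[["T"]],
         fractional = lm * frac)
}

#' Closed-form EAMSD of the shortening length
#'
#' Ensemble-averaged mean squared displacement
#' `<L^2(t)> - <L(t)>^2`. For `alpha` in (0,1):
#' `(2/Gamma(1+2a) - 1/Gamma(1+a)^2) (lambda+mu)^2 (t^a/K)^2 + s2 t^a/(K Gamma(1+a))`.
#' For the finite-mean Pareto family the full four-term expression combining
#' the linear, `t^(2-alpha)`, `t^(3-alpha)` and `t^(4-2*alpha)` contributions
#' is the default; limit branches on request.
#'
#' @inheritParams meanAnalytic
#' @param convention `"macroscopic"` uses `sigma^2` as the jump variance in
#'   diffusive terms (the macroscopic-equation convention); `"exact"` uses
#'   the full Normal+Poisson variance `sigma^2 + lambda`
#' @return EAMSD values (bp^2)
#' @export
eamsdAnalytic <- function(wait, jump, t, branch = c("full", "normal", "fractional"),
                          convention = c("macroscopic", "exact")) {
  branch <- match.arg(branch)
  stopifnot(all(t > 0))
  lm <- jumpMean(jump)
  s2 <- jumpVar(jump, convention)
  if (is(wait, "PowerLawWait")) {
    a <- wait@alpha
    K <- lowTailCoefficient(wait)
    return((2 / gamma(1 + 2 * a) - 1 / gamma(1 + a)^2) * lm^2 * (t^a / K)^2 +
             s2 * t^a / (K * gamma(1 + a)))
  }
  if (!is(wait, "ParetoWait"))
    stop("closed-form moments are available for the power-law families only")
  ct <- ctCoefficients(wait)
  a <- wait@alpha
  Tm <- ct[["T"]]; Cc <- ct[["C"]]
  lin <- s2 * t / Tm
  t2a <- Cc * s2 * t^(2 - a) / (Tm^2 * gamma(3 - a))
  t3a <- 2 * Cc * lm^2 * t^(3 - a) / (Tm^3 * gamma(4 - a))
  t4a <- (2 / gamma(5 - 2 * a) - 1 / gamma(3 - a)^2) * Cc^2 * lm^2 *
    t^(4 - 2 * a) / Tm^4
  switch(branch,
         full = lin + t2a + t3a + t4a,
         normal = lin,
         fractional = t4a + t2a)
}

#' @rdname eamsdAnalytic
#' @details `eamsdAsymptotic()` keeps only the leading long-time term of the
#'   branch selected by the regime classification: `t^(2*alpha)` for the
#'   infinite-mean family; for the Pareto family `t` (normal), `t^(4-2*alpha)`
#'   (fractional-dominated transient) or `t^(3-alpha)` (mixed) according to
#'   the `C/T` cutoffs of [classifyRegime()].
#' @param cutoffs passed to [classifyRegime()] for branch selection
#' @export
eamsdAsymptotic <- function(wait, jump, t, convention = c("macroscopic", "exact"),
                            cutoffs = c(0.1, 10)) {
  stopifnot(all(t > 0))
  lm <- jumpMean(jump)
  s2 <- jumpVar(jump, convention)
  if (is(wait, "PowerLawWait")) {
    a <- wait@alpha
    K <- lowTailCoefficient(wait)
    return((2 / gamma(1 + 2 * a) - 1 / gamma(1 + a)^2) * lm^2 * (t^a / K)^2)
  }
  if (!is(wait, "ParetoWait"))
    stop("closed-form moments are available for the power-law families only")
  ct <- ctCoefficients(wait)
  a <- wait@alpha
  Tm <- ct[["T"]]; Cc <- ct[["C"]]
  r <- ct[["ratio"]]
  if (r < cutoffs[1L]) return(s2 * t / Tm)
  if (r > cutoffs[2L])
    return((2 / gamma(5 - 2 * a) - 1 / gamma(3 - a)^2) * Cc^2 * lm^2 *
             t^(4 - 2 * a) / Tm^4)
  2 * Cc * lm^2 * t^(3 - a) / (Tm^3 * gamma(4 - a))
}

## --- empirical moments -----------------------------------------------------

momentCurve <- function(times, values, kind, source) {
  new("MomentCurve", times = as.numeric(times), values = as.numeric(values),
      kind = kind, source = source, fit = list())
}

gridFromEnsemble <- function(ens, times) {
  if (any(ens@absorbed))
    stop("moment estimation requires an ensemble simulated without absorption")
  if (is.null(times))
    stop("'times' must be supplied for an Ensemble")
  vals <- vapply(times, function(t) ensembleLengthsAt(ens, t),
                 numeric(length(ens@epochs)))
  vals   # n x m matrix
}

#' @rdname eamsdEmpirical
setMethod("eamsdEmpirical", "LengthGrid", function(x, times = NULL) {
  if (nrow(x@L) < 2L) stop("at least 2 trajectories are required")
  momentCurve(x@times, colMeans(x@L^2) - colMeans(x@L)^2, "eamsd", "empirical")
})

#' @rdname eamsdEmpirical
setMethod("eamsdEmpirical", "Ensemble", function(x, times = NULL) {
  if (length(x@epochs) < 2L) stop("at least 2 trajectories are required")
  L <- gridFromEnsemble(x, times)
  momentCurve(times, colMeans(L^2) - colMeans(L)^2, "eamsd", "empirical")
})

#' @rdname meanEmpirical
setMethod("meanEmpirical", "LengthGrid", function(x, times = NULL) {
  momentCurve(x@times, colMeans(x@L), "mean", "empirical")
})

#' @rdname meanEmpirical
setMethod("meanEmpirical", "Ensemble", function(x, times = NULL) {
  L <- gridFromEnsemble(x, times)
  momentCurve(times, colMeans(L), "mean", "empirical")
})

#' Fit a log-log power-law slope to a moment curve
#'
#' Ordinary least squares of `log(value)` on `log(t)` inside the window;
#' the default window is the final decade of the grid, chosen to dodge
#' pre-asymptotic bias.
#'
#' @param curve a [MomentCurve-class]
#' @param window time interval `c(lo, hi)`; default `c(max(t)/10, max(t))`
#' @param minPoints minimum number of grid points required in the window
#' @return list with elements `slope`, `intercept` (log-log) and `window`
#' @export
fitLogLogSlope <- function(curve, window = NULL, minPoints = 10L) {
  tmax <- max(curve@times)
  if (is.null(window)) window <- c(tmax / 10, tmax)
  inw <- curve@times >= window[1L] & curve@times <= window[2L]
  if (sum(inw) < minPoints)
    stop(sprintf("need at least %d grid points in the fit window", minPoints))
  v <- curve@values[inw]
  if (any(v <= 0)) stop("nonpositive values in the fit window")
  fit <- lm(log(v) ~ log(curve@times[inw]))
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       window = window)
}

## --- regime classification -------------------------------------------------

regimeLabel <- function(regime, exponent, ctRatio = NA_real_) {
  new("RegimeLabel", regime = regime, exponent = exponent, ctRatio = ctRatio)
}

labelFromExponent <- function(expo) {
  if (expo < 1) "subdiffusive" else if (expo > 1) "superdiffusive" else "normal"
}

#' @rdname classifyRegime
setMethod("classifyRegime", "PowerLawWait", function(model, cutoffs, horizon) {
  expo <- 2 * model@alpha
  regimeLabel(labelFromExponent(expo), expo)
})

#' @rdname classifyRegime
setMethod("classifyRegime", "ParetoWait", function(model, cutoffs, horizon) {
  ct <- ctCoefficients(model)
  r <- ct[["ratio"]]
  a <- model@alpha
  if (r < cutoffs[1L]) return(regimeLabel("normal", 1, r))
  if (r > cutoffs[2L]) {
    expo <- 4 - 2 * a
    return(regimeLabel(labelFromExponent(expo), expo, r))
  }
  regimeLabel("mixed", 3 - a, r)
})

#' @rdname classifyRegime
setMethod("classifyRegime", "TemperedWait", function(model, cutoffs, horizon) {
  if (model@xi == 0)
    return(regimeLabel(labelFromExponent(2 * model@gamma), 2 * model@gamma))
  if (is.null(horizon))
    stop("tempered laws are classified relative to the observation horizon; ",
         "supply 'horizon'")
  ## heuristic: anomalous statistics persist up to the tempering time 1/xi
  if (horizon > 1 / model@xi) regimeLabel("normal", 1)
  else regimeLabel(labelFromExponent(2 * model@gamma), 2 * model@gamma)
})
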