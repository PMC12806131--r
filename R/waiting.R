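## Inter-division waiting-time laws: constructors, samplers, transforms.

#' Heavy-tailed waiting-time law without a mean
#'
#' Pareto law with shape `alpha` in (0,1) and scale `t0`. The default scale
#' `t0 = Gamma(1-alpha)^(-1/alpha)` makes the small-s Laplace transform
#' exactly `1 - s^alpha + O(s)`, so times are measured in the natural units
#' of the fractional dynamics.
#'
#' @param alpha tail exponent in (0, 1)
#' @param t0 scale (time units); see default above
#' @return a [PowerLawWait-class] object
#' @examples
#' w <- powerLawWait(0.7)
#' waitLaplace(w, 0)   # 1
#' @export
powerLawWait <- function(alpha, t0 = gamma(1 - alpha)^(-1 / alpha)) {
  new("PowerLawWait", alpha = as.numeric(alpha), t0 = as.numeric(t0))
}

#' Finite-mean Pareto waiting-time law
#'
#' Pareto law with shape `alpha` in (1,2) and scale `tau0`: mean
#' `T = alpha*tau0/(alpha-1)` is finite, the variance is infinite, and the
#' small-s Laplace transform is `1 - T s + C s^alpha` with
#' `C = |Gamma(1-alpha)|*tau0^alpha`.
#'
#' @param alpha tail exponent in (1, 2)
#' @param tau0 time scale factor
#' @return a [ParetoWait-class] object
#' @export
paretoWait <- function(alpha, tau0 = 1) {
  new("ParetoWait", alpha = as.numeric(alpha), tau0 = as.numeric(tau0))
}

#' Tempered one-sided stable waiting-time law
#'
#' Waiting-time law with Laplace transform
#' `exp(-B^gamma*(s+xi)^gamma + B^gamma*xi^gamma)`: a one-sided
#' `gamma`-stable law of scale `B` whose power-law tail is cut off
#' exponentially at rate `xi`. Anomalous renewal statistics persist up to
#' times of order `1/xi` and become normal beyond.
#'
#' @param gamma stability index in (0, 1)
#' @param B scale (time units)
#' @param xi tempering rate (inverse time), `xi >= 0`
#' @return a [TemperedWait-class] object
#' @export
temperedWait <- function(gamma = 0.7, B = 1, xi = 0.1) {
  new("TemperedWait", gamma = as.numeric(gamma), B = as.numeric(B),
      xi = as.numeric(xi))
}

## --- internal helpers ------------------------------------------------------

## Kanter/Zolotarev auxiliary function for the one-sided gamma-stable law
## with Laplace transform exp(-s^gamma).
stableA <- function(u, gamma) {
  sin(gamma * u)^(gamma / (1 - gamma)) * sin((1 - gamma) * u) /
    sin(u)^(1 / (1 - gamma))
}

## Exact sampler (Kanter): S = (A(U)/E)^((1-gamma)/gamma), U ~ U(0,pi).
rStableOneSided <- function(n, gamma) {
  u <- runif(n, 0, pi)
  e <- rexp(n)
  (stableA(u, gamma) / e)^((1 - gamma) / gamma)
}

## Density of the standard one-sided stable law (Zolotarev integral).
dStableOneSided <- function(x, gamma) {
  vapply(x, function(xi) {
    if (xi <= 0) return(0)
    r <- xi^(-gamma / (1 - gamma))
    val <- integrate(function(u) {
      a <- stableA(u, gamma)
      a * exp(-a * r)
    }, 0, pi, rel.tol = 1e-9, stop.on.error = FALSE)$value
    gamma / (1 - gamma) * r / xi * val / pi
  }, numeric(1))
}

## Upper incomplete gamma with (possibly negative, non-integer) order.
gammaIncUpper <- function(a, x) {
  if (a > 0) return(pgamma(x, a, lower.tail = FALSE) * gamma(a))
  ## downward recurrence Gamma(a, x) = (Gamma(a+1, x) - x^a exp(-x)) / a
  (gammaIncUpper(a + 1, x) - x^a * exp(-x)) / a
}

paretoLaplace <- function(s, alpha, x0) {
  vapply(s, function(si) {
    if (si == 0) return(1)
    x <- si * x0
    alpha * x^alpha * gammaIncUpper(-alpha, x)
  }, numeric(1))
}

## --- sampleWait ------------------------------------------------------------

checkN <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("'n' must be a positive count")
  as.integer(n)
}

#' @rdname sampleWait
setMethod("sampleWait", "PowerLawWait", function(model, n, seed = NULL) {
  n <- checkN(n)
  if (!is.null(seed)) set.seed(seed)
  model@t0 * runif(n)^(-1 / model@alpha)
})

#' @rdname sampleWait
setMethod("sampleWait", "ParetoWait", function(model, n, seed = NULL) {
  n <- checkN(n)
  if (!is.null(seed)) set.seed(seed)
  model@tau0 * runif(n)^(-1 / model@alpha)
})

#' @rdname sampleWait
setMethod("sampleWait", "TemperedWait", function(model, n, seed = NULL) {
  n <- checkN(n)
  if (!is.null(seed)) set.seed(seed)
  ## exponential tilting by rejection: draw S ~ B * stable(gamma), accept
  ## with probability exp(-xi * S); the tilting constant exp((B*xi)^gamma)
  ## is absorbed by the rejection loop.
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- model@B * rStableOneSided(length(todo), model@gamma)
    acc <- runif(length(todo)) < exp(-model@xi * cand)
    out[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }
  out
})

## --- waitPDF ---------------------------------------------------------------

#' @rdname waitPDF
setMethod("waitPDF", "PowerLawWait", function(model, t, ...) {
  ifelse(t >= model@t0, model@alpha * model@t0^model@alpha * t^(-(1 + model@alpha)), 0)
})

#' @rdname waitPDF
setMethod("waitPDF", "ParetoWait", function(model, t, ...) {
  ifelse(t >= model@tau0, model@alpha * model@tau0^model@alpha * t^(-(1 + model@alpha)), 0)
})

#' @rdname waitPDF
#' @param method for `TemperedWait`: `"zolotarev"` evaluates the density
#'   exactly through the integral representation of the one-sided stable
#'   density (default); `"none"` returns `NA` (no elementary closed form
#'   exists)
setMethod("waitPDF", "TemperedWait", function(model, t, method = c("zolotarev", "none")) {
  method <- match.arg(method)
  if (method == "none") return(rep(NA_real_, length(t)))
  tilt <- exp((model@B * model@xi)^model@gamma - model@xi * t)
  tilt * dStableOneSided(t / model@B, model@gamma) / model@B
})

## --- waitLaplace -----------------------------------------------------------

#' @rdname waitLaplace
setMethod("waitLaplace", "PowerLawWait", function(model, s) {
  paretoLaplace(s, model@alpha, model@t0)
})

#' @rdname waitLaplace
setMethod("waitLaplace", "ParetoWait", function(model, s) {
  paretoLaplace(s, model@alpha, model@tau0)
})

#' @rdname waitLaplace
setMethod("waitLaplace", "TemperedWait", function(model, s) {
  exp(-model@B^model@gamma * (s + model@xi)^model@gamma +
        (model@B * model@xi)^model@gamma)
})

## --- waitSurvival ----------------------------------------------------------

#' @rdname waitSurvival
setMethod("waitSurvival", "PowerLawWait", function(model, t) {
  pmin(1, (model@t0 / pmax(t, model@t0))^model@alpha)
})

#' @rdname waitSurvival
setMethod("waitSurvival", "ParetoWait", function(model, t) {
  pmin(1, (model@tau0 / pmax(t, model@tau0))^model@alpha)
})

#' @rdname waitSurvival
setMethod("waitSurvival", "TemperedWait", function(model, t) {
  tiltC <- exp((model@B * model@xi)^model@gamma)
  vapply(t, function(ti) {
    if (ti <= 0) return(1)
    val <- integrate(function(u) {
      exp(-model@xi * u) * dStableOneSided(u / model@B, model@gamma) / model@B
    }, ti, Inf, rel.tol = 1e-7, stop.on.error = FALSE)$value
    min(1, tiltC * val)
  }, numeric(1))
})

## --- waitMean --------------------------------------------------------------

#' @rdname waitMean
setMethod("waitMean", "PowerLawWait", function(model) Inf)

#' @rdname waitMean
setMethod("waitMean", "ParetoWait", function(model) {
  model@alpha * model@tau0 / (model@alpha - 1)
})

#' @rdname waitMean
setMethod("waitMean", "TemperedWait", function(model) {
  if (model@xi == 0) return(Inf)
  model@gamma * model@B^model@gamma * model@xi^(model@gamma - 1)
})

## --- derived coefficients --------------------------------------------------

#' Fractional coefficient and mean-wait competition ratio
#'
#' For the finite-mean Pareto family, `C = |Gamma(1-alpha)|*tau0^alpha` is the
#' coefficient of the fractional `s^alpha` term in the Laplace expansion and
#' `T` is the mean wait; their ratio `C/T` selects the diffusion regime.
#'
#' @param model a [ParetoWait-class] object
#' @return named numeric vector with elements `C`, `T` and `ratio`
#' @export
ctCoefficients <- function(model) {
  stopifnot(is(model, "ParetoWait"))
  Cc <- abs(gamma(1 - model@alpha)) * model@tau0^model@alpha
  Tm <- waitMean(model)
  c(C = Cc, T = Tm, ratio = Cc / Tm)
}

## Coefficient K of the s^alpha term (1 - omega_hat ~ K s^alpha) for the
## infinite-mean family; equals 1 at the default scale.
lowTailCoefficient <- function(model) {
  gamma(1 - model@alpha) * model@t0^model@alpha
}
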