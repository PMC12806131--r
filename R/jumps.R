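## Per-division shortening-length law: compound Normal + Poisson.

#' Construct the per-division shortening law
#'
#' `L = L1 + L2` base pairs per division, `L1 ~ Normal(mu, sigma^2)` from
#' incomplete end replication and `L2 ~ Poisson(lambda)` from exonuclease
#' digestion, independent. The defaults are the values used throughout the
#' simulations (`lambda = 155`, `mu = 60`, `sigma = 1`). Draws are not
#' truncated at zero: with the defaults `P(L < 0)` is astronomically small,
#' and truncation would bias the moments; a warning is emitted if user
#' parameters push `P(L < 0)` above `1e-4`.
#'
#' @param lambda Poisson intensity (bp)
#' @param mu Normal mean (bp)
#' @param sigma Normal standard deviation (bp)
#' @return a [JumpModel-class] object
#' @examples
#' j <- jumpModel()
#' jumpMean(j)      # 215
#' jumpVariance(j)  # 156
#' @export
jumpModel <- function(lambda = 155, mu = 60, sigma = 1) {
  obj <- new("JumpModel", lambda = as.numeric(lambda), mu = as.numeric(mu),
             sigma = as.numeric(sigma))
  ## normal approximation to the compound law is ample for this diagnostic
  pneg <- pnorm(0, mean = lambda + mu, sd = sqrt(sigma^2 + lambda))
  if (pneg > 1e-4)
    warning(sprintf(
      "P(shortening < 0) ~ %.2g under these parameters; negative jumps are not truncated",
      pneg))
  obj
}

#' @rdname jumpModel
#' @param model a [JumpModel-class] object
#' @export
jumpMean <- function(model) model@lambda + model@mu

#' @rdname jumpModel
#' @export
jumpVariance <- function(model) model@sigma^2 + model@lambda

#' Draw per-division shortening lengths
#'
#' @param model a [JumpModel-class] object
#' @param n number of draws
#' @param seed optional integer seed applied before sampling
#' @return numeric vector of `n` shortening lengths (bp, continuous)
#' @export
sampleJump <- function(model, n, seed = NULL) {
  n <- checkN(n)
  if (!is.null(seed)) set.seed(seed)
  rnorm(n, model@mu, model@sigma) + rpois(n, model@lambda)
}

#' Density of the per-division shortening length
#'
#' Mixture-of-Gaussians form of the Normal-Poisson convolution:
#' `sum over k of Poisson(k; lambda) * Normal(L; mu + k, sigma^2)`, with the
#' Poisson series truncated where the remaining mass drops below `1e-12`.
#'
#' @param model a [JumpModel-class] object
#' @param L lengths at which to evaluate (bp, vectorised)
#' @return density values
#' @export
jumpPDF <- function(model, L) {
  ## truncate the Poisson series at cumulative mass 1 - 1e-12
  lo <- max(0, floor(model@lambda - 10 * sqrt(model@lambda) - 10))
  hi <- ceiling(model@lambda + 10 * sqrt(model@lambda) + 10)
  while (ppois(lo, model@lambda) > 1e-13 && lo > 0) lo <- max(0, lo - 10)
  while (ppois(hi, model@lambda, lower.tail = FALSE) > 1e-13) hi <- hi + 10
  k <- lo:hi
  w <- dpois(k, model@lambda)
  vapply(L, function(x) sum(w * dnorm(x, model@mu + k, model@sigma)), numeric(1))
}

#' Construct the three-mechanism shortening decomposition
#'
#' Combines incomplete end replication (`L1 ~ Normal(mu1, sigma1^2)`),
#' exonuclease digestion (`L2 ~ Poisson(lambda2)`, probability `pExo`) and
#' oxidative strand damage (`L3 ~ Normal(mu3, sigma3^2)` per damaged base,
#' probability `pOx`, `nDamaged` damaged bases):
#' `L = (1/4) L1 + pExo (1/4) L2 + pOx (1/2) L3 N`.
#' The oxidative-term parameters have no canonical values and must be
#' supplied by the caller.
#'
#' @param mu1,sigma1 Normal parameters of the end-replication loss (bp)
#' @param lambda2 Poisson intensity of the exonuclease loss (bp)
#' @param mu3,sigma3 Normal parameters of the per-base oxidative loss (bp);
#'   required (no published default)
#' @param nDamaged number of damaged bases `N`
#' @param pExo probability of exonuclease action (default 0.8)
#' @param pOx probability of oxidative damage (default 0.1)
#' @return a [ThreeMechanismModel-class] object
#' @export
threeMechanismModel <- function(mu1 = 60, sigma1 = 1, lambda2 = 155,
                                mu3 = NULL, sigma3 = NULL, nDamaged = 0,
                                pExo = 0.8, pOx = 0.1) {
  if (pOx > 0 && nDamaged > 0 && (is.null(mu3) || is.null(sigma3)))
    stop("oxidative-term parameters 'mu3' and 'sigma3' must be supplied ",
         "when pOx > 0 and nDamaged > 0")
  if (is.null(mu3)) mu3 <- 0
  if (is.null(sigma3)) sigma3 <- 0
  new("ThreeMechanismModel", mu1 = as.numeric(mu1), sigma1 = as.numeric(sigma1),
      lambda2 = as.numeric(lambda2), mu3 = as.numeric(mu3),
      sigma3 = as.numeric(sigma3), nDamaged = as.numeric(nDamaged),
      pExo = as.numeric(pExo), pOx = as.numeric(pOx))
}

#' Draw shortening lengths under the three-mechanism decomposition
#'
#' @param model a [ThreeMechanismModel-class] object
#' @param n number of draws
#' @param seed optional integer seed applied before sampling
#' @return numeric vector of `n` shortening lengths (bp)
#' @export
sampleThreeMechanism <- function(model, n, seed = NULL) {
  n <- checkN(n)
  if (!is.null(seed)) set.seed(seed)
  l1 <- rnorm(n, model@mu1, model@sigma1)
  l2 <- rpois(n, model@lambda2)
  ox <- if (model@pOx > 0 && model@nDamaged > 0)
    model@pOx * 0.5 * rnorm(n, model@mu3, model@sigma3) * model@nDamaged
  else 0
  0.25 * l1 + model@pExo * 0.25 * l2 + ox
}
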