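## Fractional Fokker-Planck solvers for the shortening-length density.
##
## All fractional operators use the explicit Gruenwald-Letnikov (GL)
## discretisation on the full uniform history (optionally truncated), the
## simplest scheme whose O(dt) error is testable against closed forms.

#' Gruenwald-Letnikov weights
#'
#' Binomial weights `w_k = (-1)^k choose(order, k)` computed by the stable
#' recurrence `w_k = w_{k-1} (1 - (order+1)/k)`.
#'
#' @param order derivative order
#' @param n number of weights (k = 0, ..., n-1)
#' @return numeric vector of length `n`
#' @export
glWeights <- function(order, n) {
  w <- numeric(n)
  w[1L] <- 1
  if (n > 1L) for (k in seq_len(n - 1L)) w[k + 1L] <- w[k] * (1 - (order + 1) / k)
  w
}

## linear convolution of f with w (first length(f) terms), FFT above a cutoff
convFirst <- function(f, w) {
  n <- length(f)
  if (n < 256L) {
    out <- numeric(n)
    for (j in seq_len(n)) out[j] <- sum(w[seq_len(j)] * f[j:1])
    return(out)
  }
  m <- stats::nextn(2L * n)
  zf <- complex(real = c(f, numeric(m - n)))
  zw <- complex(real = c(w[seq_len(n)], numeric(m - n)))
  out <- stats::fft(stats::fft(zf) * stats::fft(zw), inverse = TRUE) / m
  Re(out[seq_len(n)])
}

#' Tempered (substantial) fractional derivative of a time series
#'
#' Gruenwald-Letnikov approximation of the tilted Riemann-Liouville
#' derivative `exp(-tilt*t) D_t^order [exp(tilt*t) f(t)]`, i.e. the operator with
#' exponentially weighted memory kernel `exp(-tilt*(t-tau))`: at the `j`-th
#' grid time the output is
#' `dt^(-order) * sum_k w_k exp(-tilt*k*dt) f_(j-k)`.
#' With `tilt = 0` this is exactly the Riemann-Liouville derivative scheme.
#' The tilt may be complex (Fourier-mode functional weight `xi - i p U`).
#'
#' @param history values of the function on the uniform grid `t = 0, dt, ...`
#'   (the first entry is the value at `t = 0`)
#' @param order derivative order in (0, 1)
#' @param dt time step
#' @param tilt exponential tilting rate (possibly complex); default 0
#' @return the derivative values on the same grid
#' @export
substantialDerivative <- function(history, order, dt, tilt = 0) {
  if (order <= 0 || order >= 1) stop("'order' must lie in (0, 1)")
  n <- length(history)
  if (n == 0L) return(history)
  w <- glWeights(order, n) * exp(-tilt * dt * (seq_len(n) - 1L))
  if (is.complex(history) || is.complex(w)) {
    out <- vapply(seq_len(n), function(j) sum(w[seq_len(j)] * history[j:1]),
                  complex(1))
    return(out * dt^(-order))
  }
  convFirst(history, w) * dt^(-order)
}

#' @rdname substantialDerivative
#' @details `riemannLiouville()` is the untilted special case used by the
#'   Fokker-Planck solvers.
#' @export
riemannLiouville <- function(history, order, dt) {
  substantialDerivative(history, order, dt, tilt = 0)
}

## ---------------------------------------------------------------------------
## Fokker-Planck solver
## ---------------------------------------------------------------------------

## effective one-step amplification of the memory operator at step size dt
fpeEffectiveStep <- function(regime, dt, alpha, ctRatio) {
  switch(regime,
         subdiffusive = dt^alpha,                       # dt * dt^(alpha-1)
         normal = dt,
         fractional = ctRatio * dt^(2 - alpha),
         composite = dt + ctRatio * dt^(2 - alpha))
}

fpeStability <- function(regime, dt, dL, a, D, alpha, ctRatio) {
  eff <- fpeEffectiveStep(regime, dt, alpha, ctRatio)
  a * eff / dL + 2 * D * eff / dL^2
}

#' Solve a shortening-length Fokker-Planck equation
#'
#' Explicit time stepping with first-order upwind advection and centred
#' diffusion acting on the memory-operator output, with absorbing boundaries
#' (density is removed outside `[0, l0 - lc]`) and a delta initial condition
#' realised as unit mass in the first cell (`L = 0` is a cell centre).
#' The `"normal"` regime instead advances the advection by an exact
#' semi-Lagrangian shift (default: unit Courant number) split from the
#' explicit diffusion step; in this strongly advection-dominated setting an
#' upwind step below unit Courant number would add numerical diffusion far
#' exceeding the physical `s2/(2T)`.
#'
#' Regimes (selected automatically from the waiting-time law by default):
#' \describe{
#'   \item{`"subdiffusive"`}{infinite-mean power-law waits: coefficients
#'     `lambda+mu` and `s2/2` act on `D_t^(1-alpha) p` (scaled by the tail
#'     coefficient `K` for non-default `t0`).}
#'   \item{`"composite"`}{finite-mean Pareto waits: `(lambda+mu)/T` and
#'     `s2/(2T)` act on `(1 + (C/T) D_t^(alpha-1)) p`.}
#'   \item{`"normal"`}{the `C/T << 1` limit: a standard convection-diffusion
#'     equation.}
#'   \item{`"fractional"`}{the `C/T >> 1` limit: coefficients act on
#'     `(C/T) D_t^(alpha-1) p` only.}
#' }
#' The fractional memory at the absorbing wall uses the zero-extended
#' interior history (density outside the band contributes nothing), a
#' modelling choice documented in the package vignette.
#'
#' @param jump a [JumpModel-class]
#' @param wait a [WaitingTimeModel-class] (power-law families)
#' @param cfg a [TelomereConfig-class] (sets the absorbing threshold)
#' @param tMax final time
#' @param nL number of spatial cells
#' @param regime one of `"auto"`, `"subdiffusive"`, `"composite"`,
#'   `"normal"`, `"fractional"`
#' @param dt time step; default chosen so the effective Courant number equals
#'   `courant`
#' @param Lmax domain upper edge (default the absorbing threshold)
#' @param absorb absorbing boundaries? `FALSE` solves on `[0, Lmax]` with the
#'   same zero-outside convention but is intended for wide domains where the
#'   boundary is never reached
#' @param snapshotTimes times at which to store the density (default `tMax`)
#' @param courant target effective Courant number for the automatic `dt`
#' @param convention jump-variance convention, see [eamsdAnalytic()]
#' @param histLen memory truncation length in steps (default full history)
#' @return an [FPESolution-class]
#' @export
solveFPE <- function(jump, wait, cfg, tMax, nL = 200L,
                     regime = c("auto", "subdiffusive", "composite",
                                "normal", "fractional"),
                     dt = NULL, Lmax = NULL, absorb = TRUE,
                     snapshotTimes = tMax, courant = 0.4,
                     convention = c("macroscopic", "exact"), histLen = Inf) {
  regime <- match.arg(regime)
  if (regime == "auto")
    regime <- if (is(wait, "PowerLawWait")) "subdiffusive" else "composite"
  if (is(wait, "PowerLawWait") && regime != "subdiffusive")
    stop("infinite-mean waits admit the 'subdiffusive' regime only")
  if (is(wait, "TemperedWait"))
    stop("use the Feynman-Kac solver for tempered waits")

  lm <- jumpMean(jump)
  s2 <- jumpVar(jump, match.arg(convention))
  if (regime == "subdiffusive") {
    K <- lowTailCoefficient(wait)
    a <- lm / K; D <- s2 / (2 * K)
    alpha <- wait@alpha
    memOrder <- 1 - alpha        # D_t^(1-alpha)
    ctRatio <- NA_real_
  } else {
    ct <- ctCoefficients(wait)
    a <- lm / ct[["T"]]; D <- s2 / (2 * ct[["T"]])
    alpha <- wait@alpha
    memOrder <- alpha - 1        # D_t^(alpha-1)
    ctRatio <- ct[["ratio"]]
  }

  thr <- shortenThreshold(cfg)
  if (is.null(Lmax)) Lmax <- thr
  nL <- as.integer(nL)
  dL <- Lmax / (nL - 0.5)        # L = 0 is the first cell centre
  L <- (seq_len(nL) - 1L) * dL

  if (regime == "normal") {
    ## advection-dominated split scheme: exact unit-Courant shift plus
    ## explicit diffusion; the final time is rounded to a whole number of
    ## unit-Courant steps when dt is chosen automatically
    if (is.null(dt)) {
      dt <- dL / a
      nt <- max(1L, round(tMax / dt))
    } else {
      nt <- round(tMax / dt)
      if (abs(nt * dt - tMax) > 1e-9 * tMax)
        stop("'tMax' must be an integer multiple of 'dt'")
    }
    nuD <- D * dt / dL^2
    if (nuD > 0.5 + 1e-9)
      stop(sprintf("stability violation: diffusion number %.3f > 0.5; reduce dt or coarsen the grid", nuD))
  } else {
    if (is.null(dt)) {
      f <- function(ldt) fpeStability(regime, exp(ldt), dL, a, D, alpha, ctRatio) - courant
      dt <- exp(stats::uniroot(f, c(log(1e-12), log(tMax)))$root)
      nt <- ceiling(tMax / dt)
      dt <- tMax / nt
    } else {
      nt <- round(tMax / dt)
      if (abs(nt * dt - tMax) > 1e-9 * tMax)
        stop("'tMax' must be an integer multiple of 'dt'")
    }
    cn <- fpeStability(regime, dt, dL, a, D, alpha, ctRatio)
    if (cn > 1 + 1e-9)
      stop(sprintf("stability violation: effective Courant number %.3f > 1; reduce dt", cn))
  }

  snapshotTimes <- sort(unique(snapshotTimes))
  snapIdx <- pmin(nt, pmax(1L, round(snapshotTimes / dt)))
  fracScheme <- regime != "normal"
  nw <- if (fracScheme) min(nt + 1L, if (is.finite(histLen)) histLen else nt + 1L) else 0L
  w <- if (fracScheme) glWeights(memOrder, nw) else NULL

  P <- if (fracScheme) matrix(0, nL, nt + 1L) else NULL
  p <- numeric(nL)
  p[1L] <- 1 / dL                 # delta at L = 0: unit mass in the first cell
  if (fracScheme) P[, 1L] <- p
  surv <- numeric(nt)
  snaps <- matrix(0, nL, length(snapIdx))

  dtm <- if (fracScheme) dt^(-memOrder) else 0
  if (regime == "normal") {
    shift <- a * dt / dL
    sInt <- floor(shift + 1e-12)
    frac <- shift - sInt
    nuD <- D * dt / dL^2
  }
  for (n in seq_len(nt)) {
    if (regime == "normal") {
      ## semi-Lagrangian advection (exact when the shift is integer)
      lag <- function(q, k) if (k <= 0) q else c(numeric(k), q[seq_len(nL - k)])
      p <- (1 - frac) * lag(p, sInt) + frac * lag(p, sInt + 1L)
      pl <- c(0, p[-nL]); pr <- c(p[-1L], 0)
      p <- p + nuD * (pr - 2 * p + pl)
    } else {
      F <- {
        k <- min(n, nw)
        mem <- dtm * as.vector(P[, n:(n - k + 1L), drop = FALSE] %*% w[seq_len(k)])
        switch(regime,
               subdiffusive = mem,
               composite = p + ctRatio * mem,
               fractional = ctRatio * mem)
      }
      Fl <- c(0, F[-nL])            # absorbing ghost at the left wall
      Fr <- c(F[-1L], 0)            # absorbing ghost beyond Lmax
      p <- p + dt * (-a * (F - Fl) / dL + D * (Fr - 2 * F + Fl) / dL^2)
      P[, n + 1L] <- p
    }
    surv[n] <- sum(p) * dL
    hit <- which(snapIdx == n)
    if (length(hit)) snaps[, hit] <- p
  }

  new("FPESolution", L = L, times = snapIdx * dt, p = snaps,
      survivalTimes = seq_len(nt) * dt, survival = surv, regime = regime,
      dt = dt)
}

#' Surviving probability mass of a Fokker-Planck solution
#'
#' `sum(p(L, t)) * dL`, the probability that the shortening length has not
#' yet been absorbed at the critical threshold by time `t` (linearly
#' interpolated between time steps).
#'
#' @param sol an [FPESolution-class]
#' @param t times within the solved range
#' @return survival probabilities
#' @export
survivalFromFPE <- function(sol, t) {
  stopifnot(all(t >= 0), all(t <= max(sol@survivalTimes) + 1e-9))
  stats::approx(c(0, sol@survivalTimes), c(1, sol@survival), xout = t,
                rule = 2)$y
}
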