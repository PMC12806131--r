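## shared fixtures: the default jump law, canonical geometries, and a
## cheap deterministic ensemble builder for functional edge cases

defaultJump <- jumpModel()
defaultCfg <- telomereConfig()          # threshold 7000 bp

## hand-built ensemble with unit waits and unit jumps (n copies)
unitStepEnsemble <- function(n = 5L, steps = 10L, horizon = steps + 0.5) {
  new("Ensemble",
      epochs = rep(list(as.numeric(seq_len(steps))), n),
      lengths = rep(list(as.numeric(seq_len(steps))), n),
      absorbed = rep(FALSE, n),
      absorptionTime = rep(NA_real_, n),
      horizon = horizon, jump = defaultJump, wait = paretoWait(1.4),
      telomere = telomereConfig(l0 = steps, lc = 0), seed = 1L)
}

## canonical parameter list of a config (internal helper, used for equality)
configToListForTest <- function(cfg) telosim:::configToList(cfg)

## empirical Laplace transform with its Monte Carlo standard error
empiricalLaplace <- function(x, s) {
  vapply(s, function(si) {
    e <- exp(-si * x)
    c(mean(e), stats::sd(e) / sqrt(length(e)))
  }, numeric(2))
}

## log-log slope of the empirical survival tail between two quantile levels
empiricalTailSlope <- function(x, pLo = 0.99, pHi = 0.9999) {
  qs <- stats::quantile(x, c(pLo, pHi), names = FALSE)
  tg <- exp(seq(log(qs[1L]), log(qs[2L]), length.out = 15L))
  sv <- vapply(tg, function(t) mean(x > t), numeric(1))
  unname(coef(lm(log(sv) ~ log(tg)))[2L])
}
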