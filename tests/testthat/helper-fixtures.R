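# In-code fixtures shared across the suite.

tinyMap <- function(L = 6, nChr = 2, spacing = 10) {
  per <- L / nChr
  geneticMap(paste0("m", seq_len(L)),
             rep(paste0("chr", seq_len(nChr)), each = per),
             rep(seq(0, by = spacing, length.out = per), nChr))
}

# small cross, optionally with QTL effects
makeCross <- function(N = 60, p = 4, L = 12, seed = 1, spec = NULL,
                      rho = 0.5) {
  map <- tinyMap(L)
  g <- simulateRILGenotypes(map, N, seed)
  if (is.null(spec)) spec <- nullEffectSpec(p, rho = rho)
  y <- simulateTraits(g, spec, seed + 1000L)
  qtlCross(g, y, map)
}

# Independent likelihood oracle: the constrained model factorizes as
# f(Y[Kbar] | 1) * f(Y[K] | 1, x, Y[Kbar]); both factors are plain
# multivariate regressions fit by lm(), and -2*logLik differences reduce
# to residual cross-product determinants.
oracleLRT <- function(x, Y, act) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  Kb <- setdiff(seq_len(p), act)
  YK <- Y[, act, drop = FALSE]
  r0 <- if (length(Kb))
    stats::resid(stats::lm(YK ~ Y[, Kb, drop = FALSE]))
  else stats::resid(stats::lm(YK ~ 1))
  r1 <- if (length(Kb))
    stats::resid(stats::lm(YK ~ x + Y[, Kb, drop = FALSE]))
  else stats::resid(stats::lm(YK ~ x))
  max(nrow(Y) * (log(det(crossprod(r0))) - log(det(crossprod(r1)))), 0)
}

# exhaustive single-step backward elimination using only the oracle
oracleBackward <- function(x, Y) {
  p <- ncol(Y)
  active <- seq_len(p)
  bestk <- numeric(p)
  ord <- integer(p)
  bestk[p] <- oracleLRT(x, Y, active)
  step <- 1L
  while (length(active) > 1) {
    cand <- vapply(active, function(k)
      oracleLRT(x, Y, setdiff(active, k)), 0)
    drop <- active[which.max(cand)]       # which.max: lowest index on ties
    ord[step] <- drop
    step <- step + 1L
    active <- setdiff(active, drop)
    bestk[length(active)] <- max(cand)
  }
  ord[p] <- active
  list(bestk = bestk, order = ord)
}
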