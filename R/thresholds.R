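#' Permutation null records for genome-wide thresholds
#'
#' Permutes whole genotype rows against fixed phenotype rows (preserving
#' both the trait correlation structure and inter-locus linkage), runs the
#' full scan on each permuted data set, and records every null quantity
#' the threshold estimators need: per-k maxima over loci of the best-k
#' statistics, per-step maxima of the sequential elimination drops, and
#' genome-wide maxima of the individual-effect and single-effect
#' statistics.
#'
#' @param cross a \linkS4class{QTLCross}.
#' @param nPermutations number of permutations (default 1200).
#' @param seed integer seed; fixed seed reproduces records bit-exactly.
#' @return a \linkS4class{PermutationNull}.
#' @export
permutationNull <- function(cross, nPermutations = 1200, seed = 1) {
  stopifnot(nPermutations >= 1)
  X <- cross@genotypes
  Y <- cross@phenotypes
  N <- nrow(X); p <- ncol(Y)
  bestkMax <- matrix(NA_real_, nPermutations, p)
  stepMax <- matrix(NA_real_, nPermutations, p)
  indivMax <- numeric(nPermutations)
  singleMax <- numeric(nPermutations)
  set.seed(seed)
  for (b in seq_len(nPermutations)) {
    Xp <- X[sample.int(N), , drop = FALSE]
    res <- cpp_scan(Xp, Y, include_single = TRUE)
    bestkMax[b, ] <- apply(res$bestk, 2L, max)
    d <- res$bestk - cbind(0, res$bestk[, -p, drop = FALSE])
    stepMax[b, ] <- apply(d, 2L, max)
    indivMax[b] <- max(res$indiv)
    singleMax[b] <- max(res$single)
  }
  new("PermutationNull", bestkMax = bestkMax, stepMax = stepMax,
      indivMax = indivMax, singleMax = singleMax,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

# conservative empirical (1 - level) quantile: the ceiling((1-level)*B)-th
# ascending order statistic, clamped into [1, B]
.ostat <- function(v, level) {
  B <- length(v)
  sort(v)[min(B, max(1L, ceiling((1 - level) * B)))]
}

.checkAlpha <- function(alpha, B) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (B < 1 / alpha)
    warning("fewer than 1/alpha permutations; thresholds are coarse")
}

#' Per-k genome-wide thresholds lambda_k(alpha)
#'
#' The (1 - alpha) empirical quantile, per effect count k, of the
#' permutation maxima of the best-k statistic, so that
#' \eqn{P(\max_l T_{lk} > \lambda_k(\alpha)) \le \alpha} per k under the
#' no-QTL null.
#'
#' @param null a \linkS4class{PermutationNull}.
#' @param alpha genome-wide significance level.
#' @return numeric p-vector.
#' @export
lambdaAlpha <- function(null, alpha = 0.05) {
  .checkAlpha(alpha, null@nPermutations)
  apply(null@bestkMax, 2L, .ostat, level = alpha)
}

# Shared machinery for jointly calibrated per-column thresholds: choose a
# single order-statistic index j* so that the event {all columns <= their
# j*-th order statistic} holds in at least (1 - alpha) of the permutation
# records (the equal-probability-across-columns constraint), and report
# the implied per-column level beta = 1 - j*/B.
.jointCalibrate <- function(M, alpha) {
  B <- nrow(M)
  ranks <- apply(M, 2L, rank, ties.method = "min")
  if (!is.matrix(ranks)) ranks <- matrix(ranks, nrow = B)
  worst <- apply(ranks, 1L, max)       # smallest j covering record b
  jAlpha <- min(B, max(1L, ceiling((1 - alpha) * B)))
  jStar <- max(sort(worst)[jAlpha], jAlpha)
  list(thresholds = apply(M, 2L, function(col) sort(col)[jStar]),
       beta = 1 - jStar / B)
}

#' Jointly calibrated thresholds lambda_k(beta)
#'
#' Finds the per-family level beta <= alpha such that the per-k
#' (1 - beta) quantiles are jointly exceeded anywhere (any k, any locus)
#' in at most an alpha fraction of permutations:
#' \eqn{P(T_{lk} < \lambda_k(\beta)\ \forall l, k) \ge 1-\alpha}, with the
#' same per-family exceedance probability for every k. Solved exactly on
#' the permutation records by an order-statistic construction whose
#' resolution, 1/B, equals the resolution of the permutation sample.
#'
#' @inheritParams lambdaAlpha
#' @return list with \code{lambda} (numeric p) and \code{beta}.
#' @export
lambdaBeta <- function(null, alpha = 0.05) {
  .checkAlpha(alpha, null@nPermutations)
  cal <- .jointCalibrate(null@bestkMax, alpha)
  list(lambda = cal$thresholds, beta = cal$beta)
}

#' Genome-wide threshold tau(alpha) for individual-effect tests
#'
#' The (1 - alpha) quantile of the permutation maxima over all (locus,
#' trait) pairs of the individual-effect statistic (each effect given all
#' others), i.e. adjusted for multiplicity in both traits and loci.
#'
#' @inheritParams lambdaAlpha
#' @return scalar threshold.
#' @export
tauAlpha <- function(null, alpha = 0.05) {
  .checkAlpha(alpha, null@nPermutations)
  .ostat(null@indivMax, alpha)
}

#' Per-step thresholds for sequential effect elimination
#'
#' Permuted data are analyzed exactly as real data: at each locus the
#' least significant effect is repeatedly removed, and the statistic at
#' the step with k effects remaining is the drop
#' \eqn{T_{lk} - T_{l,k-1}}. Per-step genome-wide maxima are recorded and
#' the p step thresholds are jointly calibrated to family level alpha
#' with equal per-step exceedance probability (same scheme as
#' \code{\link{lambdaBeta}}), which accounts for the selection bias of
#' testing the least significant effect at every step.
#'
#' @inheritParams lambdaAlpha
#' @return numeric p-vector of per-step thresholds (index = number of
#'   effects remaining).
#' @export
seqThresholds <- function(null, alpha = 0.05) {
  .checkAlpha(alpha, null@nPermutations)
  .jointCalibrate(null@stepMax, alpha)$thresholds
}

#' Permutation-calibrated penalty for BIC-style elimination
#'
#' Per permutation, one-step forward selection from the no-QTL model
#' picks the best single effect anywhere in the genome; the penalty is
#' the (1 - alpha) quantile of these genome-wide maxima of the
#' single-effect statistic, adjusted for multiplicity in loci and traits.
#'
#' @inheritParams lambdaAlpha
#' @return scalar penalty.
#' @export
bicPenalty <- function(null, alpha = 0.05) {
  .checkAlpha(alpha, null@nPermutations)
  .ostat(null@singleMax, alpha)
}

#' Estimate the full threshold set for all detection procedures
#'
#' One permutation pass feeds every estimator; the returned
#' \linkS4class{ThresholdSet} records its resampling provenance (count and
#' seed) so detectors can verify they are used with matching settings.
#'
#' @param cross a \linkS4class{QTLCross}.
#' @param alpha genome-wide significance level, default 0.05.
#' @param nPermutations permutations, default 1200.
#' @param seed integer seed.
#' @param null optionally a precomputed \linkS4class{PermutationNull}
#'   (then \code{nPermutations} and \code{seed} are taken from it).
#' @return a \linkS4class{ThresholdSet}.
#' @export
estimateThresholds <- function(cross, alpha = 0.05, nPermutations = 1200,
                               seed = 1, null = NULL) {
  if (is.null(null)) null <- permutationNull(cross, nPermutations, seed)
  lb <- lambdaBeta(null, alpha)
  new("ThresholdSet",
      lambdaAlpha = lambdaAlpha(null, alpha),
      lambdaBeta = lb$lambda, beta = lb$beta,
      tauAlpha = tauAlpha(null, alpha),
      seqThresholds = seqThresholds(null, alpha),
      bicPenalty = bicPenalty(null, alpha),
      alpha = alpha, nPermutations = null@nPermutations,
      seed = null@seed)
}

#' Permutation thresholds for fixed-trait-set scans
#'
#' Genome-wide (1 - alpha) thresholds for the statistics of
#' \code{\link{scanFixedSet}}: per permutation of genotype rows, the max
#' over loci of each fixed-set statistic is recorded. Used to score the
#' oracle test of the true nonzero effect set.
#'
#' @param cross a \linkS4class{QTLCross}.
#' @param sets list of integer vectors (trait sets).
#' @param nPermutations permutations.
#' @param alpha genome-wide level.
#' @param seed integer seed.
#' @return numeric vector, one threshold per set.
#' @export
fixedSetThresholds <- function(cross, sets, nPermutations = 1200,
                               alpha = 0.05, seed = 1) {
  X <- cross@genotypes; Y <- cross@phenotypes
  N <- nrow(X)
  recs <- matrix(NA_real_, nPermutations, length(sets))
  set.seed(seed)
  for (b in seq_len(nPermutations)) {
    Xp <- X[sample.int(N), , drop = FALSE]
    for (j in seq_along(sets))
      recs[b, j] <- max(cpp_scan_fixed(Xp, Y, as.integer(sets[[j]])))
  }
  apply(recs, 2L, .ostat, level = alpha)
}

#' Generic genome-wide cutoff zeta(alpha)
#'
#' The cutoff for the genome-wide maximum of the statistic a given
#' detection procedure tests: the full-model threshold for "All", the
#' individual-effect threshold for "Indv", etc. Used by the jackknife
#' relative-frequency machinery.
#'
#' @param thresholds a \linkS4class{ThresholdSet}.
#' @param method detection method name.
#' @return scalar cutoff.
#' @export
zetaAlpha <- function(thresholds, method = "All") {
  switch(method,
         All = thresholds@lambdaAlpha[length(thresholds@lambdaAlpha)],
         Indv = thresholds@tauAlpha,
         BICdelta = thresholds@bicPenalty,
         thresholds@lambdaAlpha[length(thresholds@lambdaAlpha)])
}
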