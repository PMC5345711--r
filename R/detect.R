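# Per-locus sequential drops d[l, j] = T_{l,j} - T_{l,j-1}: the statistic
# of the least significant effect at the step with j effects remaining.
.stepDrops <- function(bestk) {
  p <- ncol(bestk)
  bestk - cbind(0, bestk[, -p, drop = FALSE])
}

# survivors at size k: the last k entries of the removal order
.survivors <- function(orderRow, k) {
  p <- length(orderRow)
  sort(orderRow[seq.int(p - k + 1, p)])
}

# k0 = argmax fk; on ties, the integer part of the mean of the smallest
# and largest maximizer (guards against both under- and over-selection)
.selectK0 <- function(f) {
  top <- which(f == max(f))
  k0 <- if (length(top) == 1L) top else (min(top) + max(top)) %/% 2L
  max(as.integer(k0), 1L)
}

.newDetection <- function(method, stat, thr, k0, traitSets, alpha, map) {
  new("QTLDetection", method = method, claimed = stat > thr,
      statistic = as.numeric(stat), threshold = as.numeric(thr),
      k0 = as.integer(k0), traitSets = traitSets, alpha = alpha, map = map)
}

#' MBP: select the effect count by maximum bootstrap power, then test
#'
#' At each locus, B nonparametric bootstrap samples (individuals drawn
#' with replacement, genotype and phenotype rows kept paired) yield
#' best-k statistics \eqn{T_k^{(b)}}; \eqn{f_k} is the proportion
#' exceeding the genome-wide threshold \eqn{\lambda_k}. The selected
#' count is \eqn{k_0 = \arg\max_k f_k}, or, on ties, the integer part of
#' the mean of the smallest and largest maximizer. The locus is claimed a
#' QTL if the original data's best-\eqn{k_0} statistic exceeds
#' \eqn{\lambda_{k_0}(\alpha)}.
#'
#' With \code{useBeta} the bootstrap exceedance uses the more stringent
#' jointly calibrated \eqn{\lambda_k(\beta)}, which keeps \eqn{f_k} away
#' from 1 when effects are moderately large; the final claim always uses
#' \eqn{\lambda_{k_0}(\alpha)}. Default: on when p > 3.
#'
#' @param cross a \linkS4class{QTLCross}.
#' @param thresholds a \linkS4class{ThresholdSet} estimated on the same
#'   data configuration.
#' @param B bootstrap sample count, default 250.
#' @param seed integer seed for the bootstrap draws.
#' @param useBeta logical; use lambda(beta) inside the bootstrap.
#' @param scan optional precomputed \linkS4class{QTLScan} of the data.
#' @return list with \code{detection} (\linkS4class{QTLDetection}) and
#'   \code{frequency} (\linkS4class{BootstrapFrequency}).
#' @export
mbpDetect <- function(cross, thresholds, B = 250, seed = 1,
                      useBeta = NULL, scan = NULL) {
  if (B < 1) stop("need at least one bootstrap sample")
  X <- cross@genotypes; Y <- cross@phenotypes
  N <- nrow(X); p <- ncol(Y); L <- ncol(X)
  if (length(thresholds@lambdaAlpha) != p)
    stop("thresholds were estimated for a different trait count")
  if (is.null(useBeta)) useBeta <- p > 3
  lam <- if (useBeta) thresholds@lambdaBeta else thresholds@lambdaAlpha
  if (is.null(scan)) scan <- scanGenome(cross)

  exceed <- matrix(0, L, p)
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(N, N, replace = TRUE)
    res <- cpp_scan(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                    include_single = FALSE)
    exceed <- exceed + sweep(res$bestk, 2L, lam, ">")
  }
  fk <- exceed / B

  k0 <- vapply(seq_len(L), function(l) .selectK0(fk[l, ]), 1L)

  stat <- scan@bestk[cbind(seq_len(L), k0)]
  thr <- thresholds@lambdaAlpha[k0]
  traitSets <- lapply(seq_len(L), function(l)
    .survivors(scan@eliminationOrder[l, ], k0[l]))
  det <- .newDetection("MBP", stat, thr, k0, traitSets,
                       thresholds@alpha, cross@map)
  list(detection = det,
       frequency = new("BootstrapFrequency", fk = fk, k0 = k0,
                       B = as.integer(B)))
}

#' All: joint test of all QTL effects
#'
#' The common multiple-trait procedure: a locus is claimed iff the
#' full-model statistic \eqn{T_{lp}} exceeds \eqn{\lambda_p(\alpha)}
#' (strict inequality).
#'
#' @param scan a \linkS4class{QTLScan}.
#' @param thresholds a \linkS4class{ThresholdSet}.
#' @return a \linkS4class{QTLDetection}.
#' @export
allDetect <- function(scan, thresholds) {
  p <- ncol(scan@bestk)
  .newDetection("All", scan@bestk[, p],
                rep(thresholds@lambdaAlpha[p], nrow(scan@bestk)),
                rep(p, nrow(scan@bestk)),
                rep(list(seq_len(p)), nrow(scan@bestk)),
                thresholds@alpha, scan@map)
}

#' Indv: individual-effect tests with a joint threshold
#'
#' A locus is claimed iff any individual-effect statistic (one effect
#' given all others) exceeds tau(alpha), which is adjusted for
#' multiplicity over both traits and loci; the exceeding traits are the
#' claimed associations directly, with no follow-up test needed.
#'
#' @inheritParams allDetect
#' @return a \linkS4class{QTLDetection}.
#' @export
indvDetect <- function(scan, thresholds) {
  tau <- thresholds@tauAlpha
  stat <- apply(scan@indiv, 1L, max)
  traitSets <- lapply(seq_len(nrow(scan@indiv)), function(l)
    which(scan@indiv[l, ] > tau))
  .newDetection("Indv", stat, rep(tau, nrow(scan@indiv)),
                vapply(traitSets, length, 1L), traitSets,
                thresholds@alpha, scan@map)
}

#' Seq: sequential removal of least significant effects
#'
#' At each locus the least significant effect (smallest drop in the joint
#' LRT) is tested and, if not significant at its per-step threshold,
#' removed; the locus is claimed when a step's drop statistic exceeds the
#' threshold for that step. Per-step thresholds come from permuted data
#' analyzed the same way (\code{\link{seqThresholds}}), so the selection
#' bias of always testing the weakest remaining effect is accounted for.
#'
#' @inheritParams allDetect
#' @return a \linkS4class{QTLDetection}.
#' @export
seqDetect <- function(scan, thresholds) {
  d <- .stepDrops(scan@bestk)
  thr <- thresholds@seqThresholds
  L <- nrow(d); p <- ncol(d)
  stat <- numeric(L); cut <- numeric(L); k0 <- integer(L)
  traitSets <- vector("list", L)
  for (l in seq_len(L)) {
    hit <- which(d[l, ] > thr)
    if (length(hit)) {
      j <- max(hit)                       # first significant step from the top
      stat[l] <- d[l, j]; cut[l] <- thr[j]; k0[l] <- j
      traitSets[[l]] <- .survivors(scan@eliminationOrder[l, ], j)
    } else {
      j <- which.max(d[l, ] - thr)
      stat[l] <- d[l, j]; cut[l] <- thr[j]; k0[l] <- 0L
      traitSets[[l]] <- integer()
    }
  }
  .newDetection("Seq", stat, cut, k0, traitSets, thresholds@alpha, scan@map)
}

#' BICdelta: backward elimination with a fixed permutation penalty
#'
#' Backward elimination at each locus retains an effect only if its
#' removal would decrease the joint LRT by more than the fixed penalty
#' (from \code{\link{bicPenalty}}); a locus is claimed iff at least one
#' effect is retained.
#'
#' @param scan a \linkS4class{QTLScan}.
#' @param penalty scalar penalty, or a \linkS4class{ThresholdSet} whose
#'   \code{bicPenalty} is used.
#' @param alpha significance level recorded in the result.
#' @return a \linkS4class{QTLDetection}.
#' @export
bicdeltaDetect <- function(scan, penalty, alpha = 0.05) {
  if (is(penalty, "ThresholdSet")) {
    alpha <- penalty@alpha
    penalty <- penalty@bicPenalty
  }
  if (penalty <= 0)
    warning("non-positive penalty: every locus will be claimed")
  d <- .stepDrops(scan@bestk)
  L <- nrow(d)
  hitAt <- apply(d, 1L, function(r) {
    h <- which(r > penalty)
    if (length(h)) max(h) else 0L       # elimination stops here
  })
  stat <- apply(d, 1L, max)
  traitSets <- lapply(seq_len(L), function(l)
    if (hitAt[l] > 0) .survivors(scan@eliminationOrder[l, ], hitAt[l])
    else integer())
  .newDetection("BICdelta", stat, rep(penalty, L), hitAt, traitSets,
                alpha, scan@map)
}

#' Run one of the five detection procedures
#'
#' Dispatch wrapper used by the evaluation drivers: scans the data (once)
#' and applies the requested procedure with the supplied thresholds.
#'
#' @param cross a \linkS4class{QTLCross}.
#' @param method one of "All", "MBP", "Indv", "Seq", "BICdelta".
#' @param thresholds a \linkS4class{ThresholdSet}.
#' @param B bootstrap count for MBP.
#' @param seed bootstrap seed for MBP.
#' @param scan optional precomputed \linkS4class{QTLScan}.
#' @param ... passed to \code{\link{mbpDetect}}.
#' @return a \linkS4class{QTLDetection}.
#' @export
detectQTL <- function(cross, method = c("MBP", "All", "Indv", "Seq",
                                        "BICdelta"),
                      thresholds, B = 250, seed = 1, scan = NULL, ...) {
  method <- match.arg(method)
  if (is.null(scan)) scan <- scanGenome(cross)
  switch(method,
         All = allDetect(scan, thresholds),
         MBP = mbpDetect(cross, thresholds, B = B, seed = seed,
                         scan = scan, ...)$detection,
         Indv = indvDetect(scan, thresholds),
         Seq = seqDetect(scan, thresholds),
         BICdelta = bicdeltaDetect(scan, thresholds))
}
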