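# labeled substreams from one master seed, kept below 2^31
.subSeed <- function(master, index, stream = 0L) {
  as.integer((as.double(master) * 7919 + as.double(index) * 104729 +
                stream * 15485863) %% 2147483629)
}

#' Upper reference bound for null relative frequencies
#'
#' The one-sided 95% normal upper bound for an estimated claim rate when
#' the true rate is \code{alpha}: \eqn{\alpha + 1.645\sqrt{\alpha(1 -
#' \alpha)/n_{sim}}}. Per-trait claim frequencies below this line on null
#' traits are consistent with the nominal level. With the defaults
#' (alpha 0.05, 250 simulations) the bound is approximately 0.0727.
#'
#' @param alpha nominal rate, default 0.05.
#' @param nsim number of simulations, default 250.
#' @return scalar bound.
#' @export
nullExceedanceBound <- function(alpha = 0.05, nsim = 250) {
  alpha + stats::qnorm(0.95) * sqrt(alpha * (1 - alpha) / nsim)
}

#' Delete-1 jackknife relative frequency of QTL claims
#'
#' Runs a detection procedure on each of the N delete-1 subsamples with
#' thresholds held fixed at those estimated on the full data. The
#' per-locus relative frequency \eqn{\hat p_l} is the fraction of
#' subsamples claiming locus l; the genome-wide \eqn{\hat p} the fraction
#' with any claim. Frequencies below \code{zeroingCutoff} are reported as
#' zero. \eqn{\hat p} is a surrogate for (not an estimate of) power:
#' subsamples are not independent replicates.
#'
#' @param cross a \linkS4class{QTLCross}.
#' @param method detection method (see \code{\link{detectQTL}}).
#' @param thresholds \linkS4class{ThresholdSet} from the full data.
#' @param B bootstrap count for MBP inside each subsample.
#' @param zeroingCutoff frequencies below this report as 0 (default 0.25).
#' @param seed master seed for the per-subsample bootstrap streams.
#' @return list with \code{phatLocus} (zeroed), \code{phatLocusRaw},
#'   \code{phat}, \code{B} (= N, delete-1), \code{scheme},
#'   \code{zeroingCutoff}.
#' @export
jackknifeFrequency <- function(cross, method = "MBP", thresholds,
                               B = 250, zeroingCutoff = 0.25, seed = 1) {
  N <- nIndividuals(cross)
  if (N - 1 <= nTraits(cross) + 2)
    stop("too few individuals for delete-1 refits")
  L <- nLoci(cross)
  claims <- matrix(FALSE, N, L)
  for (i in seq_len(N)) {
    sub <- qtlCross(cross@genotypes[-i, , drop = FALSE],
                    cross@phenotypes[-i, , drop = FALSE], cross@map)
    det <- detectQTL(sub, method, thresholds, B = B,
                     seed = .subSeed(seed, i, 3L))
    claims[i, ] <- det@claimed
  }
  raw <- colMeans(claims)
  list(phatLocus = ifelse(raw < zeroingCutoff, 0, raw),
       phatLocusRaw = raw, phat = mean(apply(claims, 1L, any)),
       B = N, scheme = "delete-1 jackknife",
       zeroingCutoff = zeroingCutoff)
}

.studyMethods <- c("All", "MBP", "Indv", "Seq", "BICdelta")

# one simulation replicate: phenotypes, thresholds, all detectors
.simulateReplicate <- function(geno, map, spec, alpha, nPermutations,
                               nBootstrap, seed, methods) {
  Y <- simulateTraits(geno, spec, .subSeed(seed, 1L, 2L))
  cross <- qtlCross(geno, Y, map)
  scan <- scanGenome(cross)
  thr <- estimateThresholds(cross, alpha, nPermutations,
                            seed = .subSeed(seed, 1L, 1L))
  out <- list(Y = Y, scan = scan, thresholds = thr, detections = list())
  for (m in methods) {
    if (m == "MBP") {
      mb <- mbpDetect(cross, thr, B = nBootstrap,
                      seed = .subSeed(seed, 1L, 3L), scan = scan)
      out$detections[[m]] <- mb$detection
      out$k0 <- mb$frequency@k0
    } else {
      out$detections[[m]] <- detectQTL(cross, m, thr, scan = scan)
    }
  }
  out
}

#' Genome-wide type I error study on synthetic null data
#'
#' Monte Carlo calibration: genotypes are simulated once from the map and
#' held fixed (the study conditions of a real mapping population); each
#' replicate draws null phenotypes, re-estimates all permutation
#' thresholds on that replicate, and runs every detector. The genome-wide
#' type I error estimate for a method is the fraction of replicates with
#' any claimed locus, with standard error \eqn{\sqrt{\hat p(1-\hat
#' p)/n_{sim}}}.
#'
#' @param map a \linkS4class{GeneticMap} (default: the desk-scale map of
#'   30 markers on 5 chromosomes).
#' @param n individuals per replicate, default 100.
#' @param spec a null \linkS4class{QTLEffectSpec} (no QTL), default 8
#'   exchangeably correlated traits.
#' @param methods detection methods to include.
#' @param nsim replicates, default 100.
#' @param alpha genome-wide level, default 0.05.
#' @param nPermutations permutations per replicate, default 300.
#' @param nBootstrap bootstrap samples for MBP, default 100.
#' @param seed master seed; per-replicate streams are derived from it.
#' @return data.frame with method, rate, se, nsim.
#' @export
type1ErrorStudy <- function(map = deskMap(), n = 100,
                            spec = nullEffectSpec(8),
                            methods = .studyMethods, nsim = 100,
                            alpha = 0.05, nPermutations = 300,
                            nBootstrap = 100, seed = 1) {
  if (length(spec@qtlLoci))
    stop("type I error study needs a null specification")
  geno <- simulateRILGenotypes(map, n, .subSeed(seed, 0L, 0L))
  hits <- matrix(FALSE, nsim, length(methods),
                 dimnames = list(NULL, methods))
  for (s in seq_len(nsim)) {
    rep <- .simulateReplicate(geno, map, spec, alpha, nPermutations,
                              nBootstrap, .subSeed(seed, s, 0L), methods)
    for (m in methods)
      hits[s, m] <- any(rep$detections[[m]]@claimed)
  }
  rate <- colMeans(hits)
  data.frame(method = methods, rate = as.numeric(rate),
             se = sqrt(rate * (1 - rate) / nsim), nsim = nsim,
             row.names = NULL)
}

#' Per-locus power study on synthetic data with QTL
#'
#' Monte Carlo power comparison on a spec with QTL: per replicate,
#' phenotypes are drawn, thresholds re-estimated, and each detector run;
#' per-locus claim rates are returned. Two oracle-style modes reproduce
#' the power-versus-model-size comparison: \code{fixedK} tests the best k
#' effects against \eqn{\lambda_k(\alpha)} for each requested k, and the
#' NZE mode tests exactly the true nonzero effect set at each QTL against
#' that fixed set's own genome-wide permutation threshold
#' (\code{\link{fixedSetThresholds}}). MBP's selected \eqn{k_0} at
#' each QTL marker is recorded per replicate.
#'
#' @inheritParams type1ErrorStudy
#' @param spec a \linkS4class{QTLEffectSpec} with at least one QTL.
#' @param fixedK integer vector of fixed effect counts to evaluate at the
#'   QTL markers (NULL for none).
#' @param nzeOracle logical, also evaluate the true-nonzero-set test.
#' @return list with \code{rates} (L x methods), \code{qtl} (data.frame
#'   of QTL marker rates incl. fixed-k and NZE modes), \code{mbpK0}
#'   (nsim x #QTL), \code{nsim}, \code{map}.
#' @export
powerStudy <- function(map = deskMap(), n = 100, spec,
                       methods = .studyMethods, nsim = 100, alpha = 0.05,
                       nPermutations = 300, nBootstrap = 100,
                       fixedK = NULL, nzeOracle = TRUE, seed = 1) {
  if (!length(spec@qtlLoci)) stop("power study needs a spec with QTL")
  geno <- simulateRILGenotypes(map, n, .subSeed(seed, 0L, 0L))
  L <- length(map@marker)
  p <- length(spec@intercepts)
  qtlIdx <- match(spec@qtlLoci, map@marker)
  nq <- length(qtlIdx)
  trueSets <- lapply(seq_len(nq), function(i) which(spec@effects[i, ] != 0))
  m <- lengths(trueSets)

  claims <- array(0, c(L, length(methods)),
                  dimnames = list(map@marker, methods))
  fixedHits <- if (length(fixedK))
    matrix(0, nq, length(fixedK), dimnames = list(spec@qtlLoci, fixedK))
  nzeHits <- rep(0, nq)
  mbpK0 <- matrix(NA_integer_, nsim, nq,
                  dimnames = list(NULL, spec@qtlLoci))

  for (s in seq_len(nsim)) {
    rep <- .simulateReplicate(geno, map, spec, alpha, nPermutations,
                              nBootstrap, .subSeed(seed, s, 0L), methods)
    for (mm in methods)
      claims[, mm] <- claims[, mm] + rep$detections[[mm]]@claimed
    if (!is.null(rep$k0)) mbpK0[s, ] <- rep$k0[qtlIdx]
    lamA <- rep$thresholds@lambdaAlpha
    if (length(fixedK))
      for (j in seq_along(fixedK)) {
        k <- fixedK[j]
        fixedHits[, j] <- fixedHits[, j] +
          (rep$scan@bestk[qtlIdx, k] > lamA[k])
      }
    if (nzeOracle) {
      crossS <- qtlCross(geno, rep$Y, map)
      nzThr <- fixedSetThresholds(crossS, trueSets[m > 0], nPermutations,
                                  alpha, seed = .subSeed(seed, s, 1L))
      j <- 0
      for (i in seq_len(nq)) {
        if (m[i] == 0) next
        j <- j + 1
        stat <- lrtJoint(geno[, qtlIdx[i]], rep$Y, trueSets[[i]])
        nzeHits[i] <- nzeHits[i] + (stat > nzThr[j])
      }
    }
  }
  qtl <- data.frame(marker = spec@qtlLoci, nze = m,
                    claims[qtlIdx, , drop = FALSE] / nsim,
                    check.names = FALSE)
  if (nzeOracle) qtl$NZEoracle <- ifelse(m > 0, nzeHits / nsim, NA)
  if (length(fixedK))
    for (j in seq_along(fixedK))
      qtl[[paste0("best", fixedK[j])]] <- fixedHits[, j] / nsim
  list(rates = claims / nsim, qtl = qtl, mbpK0 = mbpK0, nsim = nsim,
       map = map)
}
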