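#' Simulate RIL genotypes on a genetic map
#'
#' Generates fully inbred recombinant-inbred-line genotypes coded
#' +0.5/-0.5. The first marker of each chromosome is a fair Bernoulli
#' draw; along a chromosome, adjacent markers d cM apart recombine with
#' the RIL-by-selfing frequency \eqn{R = 2r/(1+2r)} where
#' \eqn{r = (1 - e^{-2d/100})/2} is the Haldane single-meiosis
#' recombination fraction. Chromosomes are independent.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param n number of individuals (>= 2).
#' @param seed integer seed; fixed seed reproduces genotypes bit-exactly.
#' @return numeric n x L matrix of +0.5/-0.5 with marker colnames.
#' @export
simulateRILGenotypes <- function(map, n, seed) {
  if (n < 2) stop("need at least 2 individuals")
  set.seed(seed)
  L <- length(map@marker)
  g <- matrix(NA_real_, n, L, dimnames = list(NULL, map@marker))
  for (chr in unique(map@chromosome)) {
    idx <- which(map@chromosome == chr)
    g[, idx[1]] <- ifelse(stats::runif(n) < 0.5, 0.5, -0.5)
    if (length(idx) > 1) {
      for (j in seq_along(idx)[-1]) {
        d <- map@position[idx[j]] - map@position[idx[j - 1]]
        R <- rilRecombinationFreq(d)
        flip <- stats::runif(n) < R
        g[, idx[j]] <- ifelse(flip, -g[, idx[j - 1]], g[, idx[j - 1]])
      }
    }
  }
  g
}

#' RIL recombination frequency between two markers
#'
#' Haldane map function composed with the RIL-by-selfing transform:
#' \eqn{r = (1 - e^{-2d/100})/2}, \eqn{R = 2r/(1+2r)}.
#'
#' @param d map distance in cM (non-negative).
#' @return recombinant fraction among RILs, in [0, 2/3).
#' @export
rilRecombinationFreq <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  r <- (1 - exp(-2 * d / 100)) / 2
  2 * r / (1 + 2 * r)
}

#' Truncate and scale fitted effects into simulation effects
#'
#' Converts fitted multivariate-regression coefficients into generative
#' QTL effects: \eqn{\gamma_{lk} = } \code{scale} \eqn{\cdot
#' \hat\beta_{lk}} where the residual-standardized magnitude
#' \eqn{|\hat\beta_{lk}|/\sqrt{\hat\sigma_{kk}}} reaches
#' \code{ratioCutoff}, and 0 otherwise. Truncation yields QTL with
#' different numbers of nonzero effects; scaling keeps simulated power
#' away from 0 and 1.
#'
#' @param betaHat (#qtl) x p matrix of fitted effects.
#' @param sigmaHat p x p fitted residual covariance (positive diagonal).
#' @param ratioCutoff standardized-magnitude cutoff, default 0.45.
#' @param scale multiplier for surviving effects, default 1/3.
#' @return list with \code{Gamma} ((#qtl) x p) and \code{nonzeroCounts}
#'   (integer per QTL).
#' @export
truncateAndScaleEffects <- function(betaHat, sigmaHat, ratioCutoff = 0.45,
                                    scale = 1 / 3) {
  betaHat <- as.matrix(betaHat)
  s <- diag(as.matrix(sigmaHat))
  if (any(s <= 0)) stop("sigmaHat must have a positive diagonal")
  if (ncol(betaHat) != length(s)) stop("dimension mismatch")
  keep <- sweep(abs(betaHat), 2L, sqrt(s), "/") >= ratioCutoff
  Gamma <- ifelse(keep, betaHat * scale, 0)
  list(Gamma = Gamma, nonzeroCounts = as.integer(rowSums(Gamma != 0)))
}

#' Simulate correlated traits under a QTL effect specification
#'
#' Row i of the phenotype matrix is \eqn{\beta_0 + \sum_l x_{il}\gamma_l +
#' \epsilon_i} with \eqn{\epsilon_i} i.i.d. multivariate normal
#' \eqn{N(0, \Sigma)}. An empty QTL set gives the null model.
#'
#' @param geno numeric N x L genotype matrix with marker colnames.
#' @param spec a \linkS4class{QTLEffectSpec} whose loci appear in
#'   \code{colnames(geno)}.
#' @param seed integer seed.
#' @return numeric N x p phenotype matrix with trait colnames T1..Tp.
#' @export
simulateTraits <- function(geno, spec, seed) {
  p <- length(spec@intercepts)
  n <- nrow(geno)
  set.seed(seed)
  E <- matrix(stats::rnorm(n * p), n, p) %*% chol(spec@Sigma)
  Y <- sweep(E, 2L, spec@intercepts, "+")
  if (length(spec@qtlLoci)) {
    miss <- setdiff(spec@qtlLoci, colnames(geno))
    if (length(miss)) stop("QTL marker not in genotypes: ", miss[1])
    Y <- Y + geno[, spec@qtlLoci, drop = FALSE] %*% spec@effects
  }
  colnames(Y) <- paste0("T", seq_len(p))
  Y
}

#' Build an effect specification emulating an e-trait study
#'
#' Constructs a \linkS4class{QTLEffectSpec} with a requested pattern of
#' nonzero effects per QTL and per-trait QTL variance fractions calibrated
#' into a target range. For a QTL with effect \eqn{\gamma} on a trait with
#' residual variance \eqn{\sigma_{kk}}, the variance fraction under
#' +0.5/-0.5 coding with balanced alleles is \eqn{h^2 =
#' (\gamma^2/4)/(\gamma^2/4 + \sigma_{kk})}; \eqn{\gamma} is solved from a
#' per-QTL \eqn{h^2} drawn uniformly in \code{targetH2Range} (equal across
#' that QTL's nonzero traits). The residual covariance is exchangeable
#' with correlation \code{rho}, or a supplied matrix.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param qtlLoci marker ids of the QTL (one per entry of
#'   \code{nzeCounts}).
#' @param p number of traits.
#' @param nzeCounts integer per QTL: number of traits with nonzero effect
#'   (0 allowed; all zero gives a null spec).
#' @param targetH2Range length-2 range of per-trait variance fractions,
#'   default c(0.002, 0.059).
#' @param rho exchangeable residual correlation, default 0.66.
#' @param Sigma optional p x p residual covariance overriding \code{rho}.
#' @param randomSign if TRUE each nonzero effect gets an independent
#'   random sign, else all positive.
#' @param seed integer seed.
#' @return a \linkS4class{QTLEffectSpec}.
#' @export
makeEffectSpec <- function(map, qtlLoci, p, nzeCounts,
                           targetH2Range = c(0.002, 0.059), rho = 0.66,
                           Sigma = NULL, randomSign = FALSE, seed = 1) {
  if (length(qtlLoci) != length(nzeCounts))
    stop("qtlLoci and nzeCounts lengths differ")
  if (any(nzeCounts > p)) stop("nonzero count cannot exceed p")
  if (targetH2Range[1] > targetH2Range[2]) stop("infeasible h2 range")
  miss <- setdiff(qtlLoci, map@marker)
  if (length(miss)) stop("QTL marker not in map: ", miss[1])
  if (is.null(Sigma)) {
    Sigma <- matrix(rho, p, p); diag(Sigma) <- 1
  }
  set.seed(seed)
  q <- length(qtlLoci)
  Gamma <- matrix(0, q, p)
  for (l in seq_len(q)) {
    m <- nzeCounts[l]
    if (m == 0) next
    traits <- sort(sample.int(p, m))
    h2 <- stats::runif(1, targetH2Range[1], targetH2Range[2])
    gam <- 2 * sqrt(diag(Sigma)[traits] * h2 / (1 - h2))
    if (randomSign) gam <- gam * sample(c(-1, 1), m, replace = TRUE)
    Gamma[l, traits] <- gam
  }
  new("QTLEffectSpec", intercepts = rep(0, p),
      qtlLoci = as.character(qtlLoci), effects = Gamma, Sigma = Sigma)
}

#' Null effect specification (no QTL)
#'
#' @param p number of traits.
#' @param rho exchangeable residual correlation.
#' @param Sigma optional residual covariance.
#' @return a \linkS4class{QTLEffectSpec} with an empty QTL set.
#' @export
nullEffectSpec <- function(p, rho = 0.66, Sigma = NULL) {
  if (is.null(Sigma)) {
    Sigma <- matrix(rho, p, p); diag(Sigma) <- 1
  }
  new("QTLEffectSpec", intercepts = rep(0, p), qtlLoci = character(),
      effects = matrix(0, 0, p), Sigma = Sigma)
}

#' Evenly spaced desk-scale genetic map
#'
#' Convenience constructor for simulation studies: \code{nChr}
#' chromosomes with \code{markersPerChr} markers at \code{spacing} cM.
#'
#' @param nChr chromosomes, default 5.
#' @param markersPerChr markers per chromosome, default 6.
#' @param spacing adjacent-marker distance in cM, default 10.
#' @return a \linkS4class{GeneticMap}.
#' @export
deskMap <- function(nChr = 5, markersPerChr = 6, spacing = 10) {
  geneticMap(
    paste0("m", seq_len(nChr * markersPerChr)),
    rep(paste0("chr", seq_len(nChr)), each = markersPerChr),
    rep(seq(0, by = spacing, length.out = markersPerChr), nChr))
}
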