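#' @import methods
#' @importFrom stats quantile rnorm runif qchisq sd cor var rbinom
#' @importFrom utils read.csv write.csv
#' @useDynLib mbpqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GeneticMap: ordered marker positions
#'
#' Ordered marker positions (centimorgan) on one or more chromosomes.
#' Markers define the scan grid: scans test marker positions only.
#'
#' @slot marker character, unique marker identifiers.
#' @slot chromosome character, chromosome of each marker.
#' @slot position numeric, genetic position in cM, nondecreasing within
#'   each chromosome.
#' @export
setClass("GeneticMap",
  representation(marker = "character", chromosome = "character",
                 position = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@marker))
      msg <- c(msg, paste0("duplicate marker id: ",
                           object@marker[duplicated(object@marker)][1]))
    if (length(object@marker) != length(object@chromosome) ||
        length(object@marker) != length(object@position))
      msg <- c(msg, "marker, chromosome and position lengths differ")
    if (any(!is.finite(object@position)) || any(object@position < 0))
      msg <- c(msg, "positions must be finite and non-negative")
    if (length(object@marker) < 2)
      msg <- c(msg, "a map needs at least 2 markers")
    for (chr in unique(object@chromosome)) {
      pos <- object@position[object@chromosome == chr]
      if (is.unsorted(pos)) {
        bad <- object@marker[object@chromosome == chr][which(diff(pos) < 0)[1] + 1]
        msg <- c(msg, paste0("unsorted positions on chromosome ", chr,
                             " at marker ", bad))
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' QTLCross: aligned genotypes, phenotypes and map for a RIL population
#'
#' Container for a biparental recombinant-inbred-line mapping population:
#' an N x L genotype matrix coded +0.5 (AA) / -0.5 (aa), an N x p matrix of
#' quantitative traits, and the genetic map of the L markers. Rows of the
#' two matrices refer to the same individuals; genotype columns follow map
#' order. Missing values are rejected, not imputed.
#'
#' @slot genotypes numeric matrix, N x L with entries in {+0.5, -0.5}.
#' @slot phenotypes numeric matrix, N x p.
#' @slot map a \linkS4class{GeneticMap} with L markers.
#' @export
setClass("QTLCross",
  representation(genotypes = "matrix", phenotypes = "matrix",
                 map = "GeneticMap"),
  validity = function(object) {
    g <- object@genotypes; y <- object@phenotypes
    msg <- NULL
    if (anyNA(g)) msg <- c(msg, "missing genotypes are not supported")
    else if (!all(g == 0.5 | g == -0.5))
      msg <- c(msg, "genotypes must be coded +0.5/-0.5")
    if (ncol(g) != length(object@map@marker))
      msg <- c(msg, "genotype column count differs from map marker count")
    if (!is.null(colnames(g)) && !identical(colnames(g), object@map@marker))
      msg <- c(msg, "genotype columns are not in map order")
    if (anyNA(y)) msg <- c(msg, "missing phenotypes are not supported")
    if (nrow(g) != nrow(y))
      msg <- c(msg, "genotype and phenotype row counts differ")
    if (ncol(y) < 1) msg <- c(msg, "at least one trait is required")
    if (nrow(y) <= ncol(y) + 2)
      msg <- c(msg, "need N > p + 2 individuals for a nonsingular residual covariance")
    if (is.null(msg)) TRUE else msg
  })

#' QTLScan: per-locus nested best-k LRT statistics
#'
#' Result of a genome scan: at each scanning locus, the joint LRT
#' statistics of the best k = 1, ..., p trait effects retained by backward
#' elimination (nondecreasing in k), the order in which effects were
#' removed, and the individual-effect (each effect given all others) and
#' single-effect (each effect alone) statistics.
#'
#' @slot bestk numeric L x p matrix, entry (l, k) = LRT of the best k
#'   effects at locus l.
#' @slot eliminationOrder integer L x p matrix, trait indices in removal
#'   order (the last column is the final survivor).
#' @slot indiv numeric L x p matrix of individual-effect LRTs.
#' @slot single numeric L x p matrix of single-effect LRTs.
#' @slot monomorphic logical L, loci with no genotype variation (stats 0).
#' @slot map the \linkS4class{GeneticMap} scanned.
#' @export
setClass("QTLScan",
  representation(bestk = "matrix", eliminationOrder = "matrix",
                 indiv = "matrix", single = "matrix",
                 monomorphic = "logical", map = "GeneticMap"),
  validity = function(object) {
    msg <- NULL
    if (any(object@bestk < -1e-8)) msg <- c(msg, "negative LRT statistic")
    nondec <- apply(object@bestk, 1L, function(r) all(diff(r) >= -1e-8))
    if (!all(nondec))
      msg <- c(msg, "best-k statistics must be nondecreasing in k")
    if (is.null(msg)) TRUE else msg
  })

#' PermutationNull: genome-wide null records from genotype permutations
#'
#' Per-permutation maxima used to calibrate every threshold: for each of B
#' permutations of whole genotype rows against fixed phenotypes, the max
#' over loci of the best-k statistic for each k, the max over loci of the
#' k-th sequential-elimination drop, and the max over (locus, trait) of
#' the individual-effect and single-effect statistics.
#'
#' @slot bestkMax numeric B x p.
#' @slot stepMax numeric B x p (sequential drop records).
#' @slot indivMax numeric B.
#' @slot singleMax numeric B.
#' @slot nPermutations integer B.
#' @slot seed integer seed used.
#' @export
setClass("PermutationNull",
  representation(bestkMax = "matrix", stepMax = "matrix",
                 indivMax = "numeric", singleMax = "numeric",
                 nPermutations = "integer", seed = "integer"),
  validity = function(object) {
    if (nrow(object@bestkMax) != object@nPermutations)
      "record count differs from nPermutations" else TRUE
  })

#' ThresholdSet: genome-wide significance thresholds
#'
#' Permutation-estimated thresholds for all detection procedures, with
#' resampling provenance. \code{lambdaAlpha[k]} is the genome-wide
#' (1 - alpha) threshold for the best-k statistic; \code{lambdaBeta} is
#' the jointly (over k and loci) calibrated version at the solved
#' per-family level beta <= alpha; \code{tauAlpha} covers the
#' individual-effect scan; \code{seqThresholds} the per-step sequential
#' drops; \code{bicPenalty} the single-best-effect forward-selection
#' penalty, which also serves as the generic genome-wide cutoff zeta.
#'
#' @slot lambdaAlpha numeric p-vector.
#' @slot lambdaBeta numeric p-vector.
#' @slot beta solved per-family level.
#' @slot tauAlpha numeric scalar.
#' @slot seqThresholds numeric p-vector.
#' @slot bicPenalty numeric scalar.
#' @slot alpha nominal genome-wide level.
#' @slot nPermutations integer.
#' @slot seed integer.
#' @export
setClass("ThresholdSet",
  representation(lambdaAlpha = "numeric", lambdaBeta = "numeric",
                 beta = "numeric", tauAlpha = "numeric",
                 seqThresholds = "numeric", bicPenalty = "numeric",
                 alpha = "numeric", nPermutations = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@lambdaAlpha, object@lambdaBeta, object@tauAlpha,
              object@seqThresholds, object@bicPenalty) < 0))
      msg <- c(msg, "thresholds must be non-negative")
    if (object@beta > object@alpha + 1e-12)
      msg <- c(msg, "joint per-family level beta cannot exceed alpha")
    if (any(object@lambdaBeta < object@lambdaAlpha - 1e-8))
      msg <- c(msg, "lambdaBeta must dominate lambdaAlpha elementwise")
    if (is.null(msg)) TRUE else msg
  })

#' QTLEffectSpec: generative model for simulated traits
#'
#' Defines the multivariate-normal trait model used by the simulator:
#' per-trait intercepts, a set of QTL markers with an effect matrix
#' (rows = QTL, columns = traits), and a positive-definite residual
#' covariance. An empty QTL set gives the null (no-QTL) model.
#'
#' @slot intercepts numeric p-vector.
#' @slot qtlLoci character, marker ids of the QTL (possibly empty).
#' @slot effects numeric (#qtl) x p matrix of effects gamma[l, k].
#' @slot Sigma numeric p x p positive-definite residual covariance.
#' @export
setClass("QTLEffectSpec",
  representation(intercepts = "numeric", qtlLoci = "character",
                 effects = "matrix", Sigma = "matrix"),
  validity = function(object) {
    msg <- NULL
    p <- length(object@intercepts)
    if (!isTRUE(all.equal(object@Sigma, t(object@Sigma), tolerance = 1e-8)))
      msg <- c(msg, "Sigma must be symmetric")
    else if (min(eigen(object@Sigma, symmetric = TRUE,
                       only.values = TRUE)$values) <= 0)
      msg <- c(msg, "Sigma must be positive definite")
    if (ncol(object@Sigma) != p)
      msg <- c(msg, "Sigma dimension differs from trait count")
    if (nrow(object@effects) != length(object@qtlLoci) ||
        (length(object@qtlLoci) > 0 && ncol(object@effects) != p))
      msg <- c(msg, "effects matrix must be (#qtl) x p")
    if (is.null(msg)) TRUE else msg
  })

#' QTLDetection: per-locus QTL claims of one detection procedure
#'
#' @slot method character, one of "All", "MBP", "Indv", "Seq", "BICdelta".
#' @slot claimed logical L.
#' @slot statistic numeric L, the statistic each claim is based on.
#' @slot threshold numeric L, the cutoff it was compared to.
#' @slot k0 integer L, selected/retained effect count (NA where the
#'   procedure has no such notion).
#' @slot traitSets list of integer vectors, the nontrivial trait set used
#'   at each locus.
#' @slot alpha genome-wide significance level.
#' @slot map the \linkS4class{GeneticMap}.
#' @export
setClass("QTLDetection",
  representation(method = "character", claimed = "logical",
                 statistic = "numeric", threshold = "numeric",
                 k0 = "integer", traitSets = "list", alpha = "numeric",
                 map = "GeneticMap"),
  validity = function(object) {
    ok <- object@claimed == (object@statistic > object@threshold)
    if (!all(ok)) "claimed must equal statistic > threshold" else TRUE
  })

#' BootstrapFrequency: bootstrap exceedance proportions and selected k0
#'
#' For each locus and effect count k, the proportion f_k of nonparametric
#' bootstrap samples in which the best-k statistic exceeded its genome-wide
#' threshold, and the selected count k0 = argmax_k f_k (ties resolved as
#' the integer part of the mean of the smallest and largest maximizer).
#'
#' @slot fk numeric L x p matrix in [0, 1].
#' @slot k0 integer L.
#' @slot B integer bootstrap count.
#' @export
setClass("BootstrapFrequency",
  representation(fk = "matrix", k0 = "integer", B = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@fk < 0 | object@fk > 1))
      msg <- c(msg, "fk entries must lie in [0, 1]")
    if (any(object@k0 < 1 | object@k0 > ncol(object@fk)))
      msg <- c(msg, "k0 out of range")
    if (is.null(msg)) TRUE else msg
  })

#' QTLAssociation: locus-by-trait association tests after QTL detection
#'
#' Result of the follow-up idv procedure: each nontrivial effect at a
#' claimed locus tested given the other nontrivial effects, against the
#' chi-square quantile at level 1 - alpha/k0 (Bonferroni over the k0
#' tested effects). Trivial traits are never tested.
#'
#' @slot table data.frame with columns marker, trait, chi2, df, cutoff,
#'   significant.
#' @slot trivialSets list of integer vectors per tested locus.
#' @slot k0 integer per tested locus.
#' @slot alpha numeric.
#' @export
setClass("QTLAssociation",
  representation(table = "data.frame", trivialSets = "list",
                 k0 = "integer", alpha = "numeric"),
  validity = function(object) {
    tb <- object@table
    if (nrow(tb) && !all(tb$significant == (tb$chi2 > tb$cutoff)))
      "significant must equal chi2 > cutoff" else TRUE
  })
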