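#' Joint likelihood-ratio test of QTL effects on a set of traits
#'
#' Tests the no-QTL model against the multivariate-normal regression model
#' in which the genotype column has effects on the traits in
#' \code{activeSet} only (effects on all other traits constrained to
#' zero). The statistic is \eqn{T = N \log(\det\hat\Sigma_0 /
#' \det\hat\Sigma_1)} with maximum-likelihood (divide-by-N) residual
#' covariance estimates, i.e. exactly \eqn{-2} times the log-likelihood
#' difference, asymptotically chi-square with \code{length(activeSet)}
#' degrees of freedom under the null.
#'
#' A monomorphic genotype column carries no information and scores 0 with
#' a warning, so resampling loops never abort on degenerate draws.
#'
#' @param genoCol numeric N-vector of coded genotypes.
#' @param Y numeric N x p phenotype matrix.
#' @param activeSet integer vector of trait indices with nonzero effects
#'   under the alternative (default: all traits).
#' @return non-negative LRT statistic.
#' @export
lrtJoint <- function(genoCol, Y, activeSet = seq_len(ncol(Y))) {
  Y <- as.matrix(Y)
  if (length(activeSet) < 1) stop("activeSet must contain at least one trait")
  if (anyDuplicated(activeSet)) stop("activeSet has duplicate entries")
  if (stats::var(genoCol) < 1e-12) {
    warning("monomorphic locus: LRT set to 0")
    return(0)
  }
  cpp_lrt_joint(as.numeric(genoCol), Y, as.integer(activeSet))
}

#' Backward elimination of QTL effects at one locus
#'
#' Starting from effects on all p traits, repeatedly removes the effect
#' whose removal reduces the joint LRT least (the least significant effect
#' given the others; ties go to the lower trait index). Returns the nested
#' best-k statistics -- \code{bestk[k]} is the joint LRT of the k
#' surviving effects -- which are nondecreasing in k, and the removal
#' order.
#'
#' @inheritParams lrtJoint
#' @return list with \code{bestk} (numeric p), \code{order} (integer p,
#'   removal order, last entry = final survivor).
#' @export
backwardEliminate <- function(genoCol, Y) {
  Y <- as.matrix(Y)
  res <- cpp_scan(matrix(as.numeric(genoCol), ncol = 1), Y,
                  include_single = FALSE)
  if (res$monomorphic[1]) warning("monomorphic locus: all statistics 0")
  list(bestk = drop(res$bestk), order = drop(res$order))
}

#' Genome scan of nested best-k LRT statistics
#'
#' Applies \code{\link{backwardEliminate}} at every marker and also
#' records, per locus, the individual-effect statistics (each effect
#' tested given all others) and single-effect statistics (each effect
#' alone, all others excluded). Deterministic given its inputs.
#'
#' @param cross a \linkS4class{QTLCross}, or a genotype matrix if \code{Y}
#'   is given.
#' @param Y phenotype matrix when \code{cross} is a plain genotype matrix.
#' @param map optional \linkS4class{GeneticMap} for the matrix interface.
#' @return a \linkS4class{QTLScan}.
#' @export
scanGenome <- function(cross, Y = NULL, map = NULL) {
  if (is(cross, "QTLCross")) {
    X <- cross@genotypes; Y <- cross@phenotypes; map <- cross@map
  } else {
    X <- as.matrix(cross)
    if (is.null(map))
      map <- geneticMap(colnames(X) %||% paste0("m", seq_len(ncol(X))),
                        rep("1", ncol(X)), seq_len(ncol(X)))
  }
  res <- cpp_scan(X, as.matrix(Y), include_single = TRUE)
  if (any(res$monomorphic))
    message(sum(res$monomorphic), " monomorphic loci scored 0")
  new("QTLScan", bestk = res$bestk, eliminationOrder = res$order,
      indiv = res$indiv, single = res$single,
      monomorphic = as.logical(res$monomorphic), map = map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome scan of a fixed active trait set
#'
#' Joint LRT of the same (known) trait set at every locus, e.g. to score
#' the oracle test that fits exactly the true nonzero effects. No model
#' selection is involved, so its genome-wide null differs from the best-k
#' null; see \code{\link{fixedSetThresholds}}.
#'
#' @param cross a \linkS4class{QTLCross}.
#' @param activeSet integer vector of trait indices.
#' @return numeric vector of per-locus statistics.
#' @export
scanFixedSet <- function(cross, activeSet) {
  drop(cpp_scan_fixed(cross@genotypes, cross@phenotypes,
                      as.integer(activeSet)))
}

#' Individual- and single-effect test statistics genome-wide
#'
#' Two per-effect statistics at every (locus, trait): \code{indiv}, the
#' LRT for one effect given all other effects in the model (the full-model
#' statistic minus the statistic without that effect), and \code{single},
#' the LRT for that effect with all other effects excluded.
#'
#' @inheritParams scanGenome
#' @return list with matrices \code{indiv} and \code{single} (L x p).
#' @export
effectTests <- function(cross, Y = NULL) {
  sc <- scanGenome(cross, Y)
  list(indiv = sc@indiv, single = sc@single)
}

#' LRT of one QTL effect given a trivial set
#'
#' Compares the model with QTL effects on all traits outside the trivial
#' set \code{trivialSet} to the same model with the effect on trait
#' \code{k} additionally constrained to zero; 1 degree of freedom. With an
#' empty trivial set this is the individual-effect test; with all other
#' traits trivial it is the single-effect test.
#'
#' @inheritParams lrtJoint
#' @param k trait index to test (not in \code{trivialSet}).
#' @param trivialSet integer vector of trait indices assumed to have no
#'   QTL effect (may be empty).
#' @return non-negative LRT statistic.
#' @export
lrtGivenTrivial <- function(genoCol, Y, k, trivialSet = integer()) {
  p <- ncol(as.matrix(Y))
  if (k %in% trivialSet) stop("tested trait cannot be in the trivial set")
  nontrivial <- setdiff(seq_len(p), trivialSet)
  full <- lrtJoint(genoCol, Y, nontrivial)
  reduced <- if (length(nontrivial) > 1)
    lrtJoint(genoCol, Y, setdiff(nontrivial, k)) else 0
  max(full - reduced, 0)
}
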