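#' idv: test individual QTL effects at a claimed locus
#'
#' For each nontrivial trait k (not in the trivial set), computes the LRT
#' for the effect on k given the other nontrivial effects (trivial
#' effects held at zero), and compares it to the chi-square quantile with
#' 1 degree of freedom at level \eqn{1 - \alpha/k_0}, Bonferroni over the
#' \eqn{k_0} tested effects. Traits in the trivial set are reported
#' non-significant without testing.
#'
#' @param genoCol numeric N-vector, genotype column of the claimed locus.
#' @param Y numeric N x p phenotype matrix.
#' @param trivialSet integer vector of traits excluded as trivial (may be
#'   empty).
#' @param alpha significance level, default 0.05.
#' @param marker optional marker label for the output table.
#' @return a \linkS4class{QTLAssociation} for the one locus.
#' @export
idvTest <- function(genoCol, Y, trivialSet = integer(), alpha = 0.05,
                    marker = "locus") {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  tested <- setdiff(seq_len(p), trivialSet)
  k0 <- length(tested)
  if (k0 == 0) stop("all effects are trivial: nothing to test")
  cutoff <- stats::qchisq(1 - alpha / k0, df = 1)
  chi2 <- vapply(tested, function(k)
    lrtGivenTrivial(genoCol, Y, k, trivialSet), 0)
  traitNames <- colnames(Y) %||% paste0("T", seq_len(p))
  tb <- data.frame(
    marker = marker,
    trait = traitNames[c(tested, trivialSet)],
    chi2 = c(chi2, rep(NA_real_, length(trivialSet))),
    df = 1L,
    cutoff = cutoff,
    significant = c(chi2 > cutoff, rep(FALSE, length(trivialSet))),
    tested = c(rep(TRUE, k0), rep(FALSE, length(trivialSet))),
    stringsAsFactors = FALSE)
  tb$chi2[is.na(tb$chi2)] <- 0
  new("QTLAssociation", table = tb, trivialSets = list(trivialSet),
      k0 = as.integer(k0), alpha = alpha)
}

#' Two-step QTL-trait association testing
#'
#' Applies \code{\link{idvTest}} at every locus a detector claimed,
#' using the detector's own nontrivial trait set: for MBP the best
#' \eqn{k_0} effects (the \eqn{p - k_0} first-eliminated traits form the
#' trivial set), for All the full set (\eqn{k_0 = p}), for Seq and
#' BICdelta the effects surviving those procedures. Unclaimed loci
#' contribute no tests, so association claims cannot raise the
#' genome-wide type I error rate for QTL detection above the detector's.
#'
#' @param detection a \linkS4class{QTLDetection}.
#' @param cross the \linkS4class{QTLCross} the detector ran on.
#' @param alpha significance level (defaults to the detector's).
#' @return a \linkS4class{QTLAssociation} covering all claimed loci
#'   (empty table if none).
#' @export
associationTests <- function(detection, cross, alpha = detection@alpha) {
  p <- nTraits(cross)
  claimed <- which(detection@claimed)
  if (!length(claimed)) {
    empty <- data.frame(marker = character(), trait = character(),
                        chi2 = numeric(), df = integer(),
                        cutoff = numeric(), significant = logical(),
                        tested = logical(), stringsAsFactors = FALSE)
    return(new("QTLAssociation", table = empty, trivialSets = list(),
               k0 = integer(), alpha = alpha))
  }
  tabs <- vector("list", length(claimed))
  triv <- vector("list", length(claimed))
  k0s <- integer(length(claimed))
  for (i in seq_along(claimed)) {
    l <- claimed[i]
    nontrivial <- detection@traitSets[[l]]
    trivialSet <- setdiff(seq_len(p), nontrivial)
    a <- idvTest(cross@genotypes[, l], cross@phenotypes, trivialSet,
                 alpha = alpha, marker = cross@map@marker[l])
    tabs[[i]] <- a@table
    triv[[i]] <- trivialSet
    k0s[i] <- a@k0
  }
  new("QTLAssociation", table = do.call(rbind, tabs), trivialSets = triv,
      k0 = k0s, alpha = alpha)
}
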