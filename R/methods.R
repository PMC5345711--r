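#' Accessors for mbpqtl objects
#'
#' Small accessor layer over the S4 containers: dimensions, component
#' matrices, and detection summaries.
#'
#' @param object an mbpqtl S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nLoci", function(object) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("nTraits", function(object) standardGeneric("nTraits"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(object) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("crossMap", function(object) standardGeneric("crossMap"))
#' @rdname accessors
#' @export
setGeneric("scanStats", function(object) standardGeneric("scanStats"))
#' @rdname accessors
#' @export
setGeneric("eliminationOrder",
           function(object) standardGeneric("eliminationOrder"))
#' @rdname accessors
#' @export
setGeneric("claimedLoci", function(object) standardGeneric("claimedLoci"))

#' @rdname accessors
setMethod("nLoci", "GeneticMap", function(object) length(object@marker))
#' @rdname accessors
setMethod("markers", "GeneticMap", function(object) object@marker)
#' @rdname accessors
setMethod("nLoci", "QTLCross", function(object) ncol(object@genotypes))
#' @rdname accessors
setMethod("nTraits", "QTLCross", function(object) ncol(object@phenotypes))
#' @rdname accessors
setMethod("nIndividuals", "QTLCross", function(object) nrow(object@genotypes))
#' @rdname accessors
setMethod("markers", "QTLCross", function(object) object@map@marker)
#' @rdname accessors
setMethod("genotypes", "QTLCross", function(object) object@genotypes)
#' @rdname accessors
setMethod("phenotypes", "QTLCross", function(object) object@phenotypes)
#' @rdname accessors
setMethod("crossMap", "QTLCross", function(object) object@map)
#' @rdname accessors
setMethod("scanStats", "QTLScan", function(object) object@bestk)
#' @rdname accessors
setMethod("eliminationOrder", "QTLScan",
          function(object) object@eliminationOrder)
#' @rdname accessors
setMethod("nLoci", "QTLScan", function(object) nrow(object@bestk))
#' @rdname accessors
setMethod("nTraits", "QTLScan", function(object) ncol(object@bestk))
#' @rdname accessors
setMethod("claimedLoci", "QTLDetection",
          function(object) object@map@marker[object@claimed])

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", length(object@marker), "markers on",
      length(unique(object@chromosome)), "chromosome(s),",
      sprintf("%.1f cM total\n",
              sum(tapply(object@position, object@chromosome,
                         function(x) max(x) - min(x)))))
})

setMethod("show", "QTLCross", function(object) {
  cat("QTLCross:", nrow(object@genotypes), "individuals,",
      ncol(object@genotypes), "markers,",
      ncol(object@phenotypes), "traits\n")
})

setMethod("show", "QTLScan", function(object) {
  L <- nrow(object@bestk); p <- ncol(object@bestk)
  cat("QTLScan:", L, "loci x", p, "traits; max full-model LRT",
      sprintf("%.2f at %s\n", max(object@bestk[, p]),
              object@map@marker[which.max(object@bestk[, p])]))
})

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet (alpha =", object@alpha, ",",
      object@nPermutations, "permutations, seed", object@seed, ")\n")
  cat("  lambda(alpha):", sprintf("%.2f", object@lambdaAlpha), "\n")
  cat("  lambda(beta): ", sprintf("%.2f", object@lambdaBeta),
      sprintf(" [beta = %.4g]\n", object@beta))
  cat("  tau(alpha):", sprintf("%.2f", object@tauAlpha),
      " BIC penalty:", sprintf("%.2f", object@bicPenalty), "\n")
})

setMethod("show", "QTLDetection", function(object) {
  cat("QTLDetection [", object@method, "]: ", sum(object@claimed), "/",
      length(object@claimed), " loci claimed at alpha = ",
      object@alpha, "\n", sep = "")
  if (any(object@claimed))
    cat("  claimed:", paste(claimedLoci(object), collapse = ", "), "\n")
})

setMethod("show", "QTLAssociation", function(object) {
  cat("QTLAssociation:", sum(object@table$significant), "significant of",
      sum(object@table$tested), "tested locus-trait pairs at alpha =",
      object@alpha, "\n")
})

setMethod("show", "BootstrapFrequency", function(object) {
  cat("BootstrapFrequency:", nrow(object@fk), "loci,", object@B,
      "bootstrap samples; k0 range", min(object@k0), "-",
      max(object@k0), "\n")
})

setMethod("show", "QTLEffectSpec", function(object) {
  nz <- if (length(object@qtlLoci)) rowSums(object@effects != 0) else integer()
  cat("QTLEffectSpec:", length(object@intercepts), "traits,",
      length(object@qtlLoci), "QTL",
      if (length(nz)) paste0("(nonzero effects: ",
                             paste(nz, collapse = ", "), ")"), "\n")
})

#' Per-locus detection summary table
#'
#' @param x a \linkS4class{QTLDetection}.
#' @param ... unused.
#' @return data.frame with marker, chromosome, position, statistic,
#'   threshold, claimed, k0 and the selected trait set.
#' @export
detectionTable <- function(x, ...) {
  data.frame(marker = x@map@marker, chromosome = x@map@chromosome,
             position_cM = x@map@position, statistic = x@statistic,
             threshold = x@threshold, claimed = x@claimed, k0 = x@k0,
             traits = vapply(x@traitSets, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}
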